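#' Resolve the loop and the two binding-site residue selections
#'
#' Region definitions use the topology's own residue numbering verbatim.
#' The three sets must be pairwise disjoint, non-empty, and every id must
#' resolve to at least one heavy atom. The returned object carries, for each
#' region and for each individual residue, the heavy-atom row indices into
#' the ensemble's atom table (hydrogen indices are attached separately for
#' the `include_hydrogens` analysis switch).
#'
#' @param ens an [ensemble].
#' @param loop,siteA,siteB integer vectors of residue ids: the mobile loop
#'   and the two competing binding sites (site A is the TYD-like site,
#'   site B the CTD-like site in the reference system).
#' @param numbering free-text label for the numbering convention.
#' @return an object of class `region_set`.
#' @export
resolve_regions <- function(ens, loop, siteA, siteB,
                            numbering = "topology numbering") {
  stopifnot(inherits(ens, "ensemble"))
  regions <- list(loop = as.integer(loop), siteA = as.integer(siteA),
                  siteB = as.integer(siteB))
  for (nm in names(regions)) {
    if (length(regions[[nm]]) == 0L) stop("region '", nm, "' is empty")
    if (anyDuplicated(regions[[nm]]))
      stop("region '", nm, "' has duplicated residue ids")
  }
  for (pair in list(c("loop", "siteA"), c("loop", "siteB"),
                    c("siteA", "siteB"))) {
    ov <- intersect(regions[[pair[1]]], regions[[pair[2]]])
    if (length(ov))
      stop("regions '", pair[1], "' and '", pair[2],
           "' overlap at residue(s) ", paste(ov, collapse = ", "))
  }
  atoms <- ens$atoms
  known <- unique(atoms$resno[atoms$heavy])
  atom_idx <- h_idx <- vector("list", 3L)
  names(atom_idx) <- names(h_idx) <- names(regions)
  for (nm in names(regions)) {
    miss <- setdiff(regions[[nm]], known)
    if (length(miss))
      stop("region '", nm, "': residue id(s) ",
           paste(miss, collapse = ", "),
           " not found in topology (or have no heavy atoms)")
    atom_idx[[nm]] <- lapply(regions[[nm]], function(r)
      which(atoms$resno == r & atoms$heavy))
    names(atom_idx[[nm]]) <- as.character(regions[[nm]])
    h_idx[[nm]] <- lapply(regions[[nm]], function(r)
      which(atoms$resno == r & !atoms$heavy))
    names(h_idx[[nm]]) <- as.character(regions[[nm]])
  }
  structure(list(loop = regions$loop, siteA = regions$siteA,
                 siteB = regions$siteB, atom_idx = atom_idx,
                 hydrogen_idx = h_idx, numbering = numbering),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("Region set (", x$numbering, ")\n", sep = "")
  cat("  loop  :", length(x$loop), "residues [",
      paste(range(x$loop), collapse = "-"), "]\n")
  cat("  siteA :", length(x$siteA), "residues [",
      paste(range(x$siteA), collapse = "-"), "]\n")
  cat("  siteB :", length(x$siteB), "residues [",
      paste(range(x$siteB), collapse = "-"), "]\n")
  invisible(x)
}

## Pooled heavy-atom indices of one region, optionally with hydrogens.
.region_atoms <- function(regions, name, include_hydrogens = FALSE) {
  idx <- unlist(regions$atom_idx[[name]], use.names = FALSE)
  if (include_hydrogens)
    idx <- c(idx, unlist(regions$hydrogen_idx[[name]], use.names = FALSE))
  idx
}

#' Analysis configuration
#'
#' Collects the tunable parameters of the contact/state/kinetics pipeline
#' with the field-standard defaults: center-distance cutoffs 6.5, 8.0 and
#' 12.0 Angstrom; a residue pair is "in contact" when any two heavy atoms
#' are within 4.5 Angstrom; a frame counts as bound when at least 3 loop
#' residues contact a site.
#'
#' @param center_cutoffs numeric, Angstrom.
#' @param atom_contact_cutoff numeric, Angstrom.
#' @param min_contact_residues integer >= 1.
#' @param bootstrap_replicates integer, bootstrap resamples for CIs.
#' @param ci_level confidence level in (0, 1).
#' @param seed integer seed for all stochastic steps.
#' @param include_hydrogens logical; if TRUE the 4.5 A pair criterion uses
#'   all atoms, not just heavy atoms.
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(center_cutoffs = c(6.5, 8.0, 12.0),
                            atom_contact_cutoff = 4.5,
                            min_contact_residues = 3L,
                            bootstrap_replicates = 10000L,
                            ci_level = 0.95, seed = 1L,
                            include_hydrogens = FALSE) {
  stopifnot(all(center_cutoffs > 0), atom_contact_cutoff > 0,
            min_contact_residues >= 1L,
            ci_level > 0, ci_level < 1, bootstrap_replicates >= 100L)
  structure(list(center_cutoffs = sort(as.numeric(center_cutoffs)),
                 atom_contact_cutoff = as.numeric(atom_contact_cutoff),
                 min_contact_residues = as.integer(min_contact_residues),
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 ci_level = as.numeric(ci_level), seed = as.integer(seed),
                 include_hydrogens = isTRUE(include_hydrogens)),
            class = "analysis_config")
}

#' Read / write the YAML analysis configuration
#'
#' The file holds the three region definitions (residue id vectors or
#' `"start-end"` range strings), the numbering label, and any analysis
#' parameters that deviate from the defaults of [analysis_config()].
#'
#' @param path YAML file path.
#' @return `read_analysis_config`: a list with elements `regions` (loop /
#'   siteA / siteB integer vectors plus `numbering`) and `config`
#'   (an [analysis_config]).
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  parse_ids <- function(x) {
    if (is.character(x) && length(x) == 1L && grepl("-", x)) {
      rng <- as.integer(strsplit(x, "-", fixed = TRUE)[[1]])
      return(seq.int(rng[1], rng[2]))
    }
    as.integer(unlist(x))
  }
  if (is.null(y$regions)) stop("config lacks a 'regions' block")
  regions <- list(loop = parse_ids(y$regions$loop),
                  siteA = parse_ids(y$regions$siteA),
                  siteB = parse_ids(y$regions$siteB),
                  numbering = y$regions$numbering %||% "topology numbering")
  defaults <- unclass(analysis_config())
  ana <- y$analysis %||% list()
  cfg <- do.call(analysis_config,
                 utils::modifyList(defaults,
                                   ana[intersect(names(ana),
                                                 names(defaults))]))
  list(regions = regions, config = cfg)
}

#' @rdname read_analysis_config
#' @param regions list with `loop`, `siteA`, `siteB` (and optionally
#'   `numbering`).
#' @param config an [analysis_config].
#' @export
write_analysis_config <- function(regions, config, path) {
  yaml::write_yaml(list(regions = regions,
                        analysis = unclass(config)), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
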