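#' Region schemes
#'
#' A `RegionScheme` maps named structural fragments of a receptor tyrosine
#' kinase cytoplasmic region (juxtamembrane fragments, kinase lobes, loops)
#' onto inclusive author-numbered residue ranges. The required names are
#' `JMR`, `JM-B`, `JM-S`, `JM-Z`, `N-lobe`, `C-lobe`, `A-loop`, `C-loop`,
#' `Ca-helix`, `P-loop`, `KID`.
#'
#' @param regions named list; each element an inclusive range `c(lo, hi)` or
#'   a matrix of such rows for disjoint ranges.
#' @param residue_span optional `c(min, max)` of the structure's residues;
#'   when given, ranges are validated against it.
#' @return object of class `RegionScheme`.
#' @export
region_scheme <- function(regions, residue_span = NULL) {
  req <- required_regions()
  missing <- setdiff(req, names(regions))
  if (length(missing))
    trj_error("trajcomm_scheme_error", "missing required region(s): %s",
              paste(missing, collapse = ", "))
  regions <- lapply(regions, function(r) {
    m <- matrix(as.integer(r), ncol = 2, byrow = !is.matrix(r))
    if (any(m[, 2] < m[, 1]))
      trj_error("trajcomm_scheme_error", "region range with hi < lo")
    m
  })
  sc <- structure(list(regions = regions, residue_span = residue_span),
                  class = "RegionScheme")
  for (sub in c("JM-B", "JM-S"))
    if (!all(region_residues(sc, sub) %in% region_residues(sc, "JMR")))
      trj_error("trajcomm_scheme_error", "%s must be a subset of JMR", sub)
  if (!is.null(residue_span)) {
    for (nm in names(regions)) {
      rr <- region_residues(sc, nm)
      if (min(rr) < residue_span[1] || max(rr) > residue_span[2])
        trj_error("trajcomm_scheme_error",
                  "region %s [%d-%d] outside structure span [%d-%d]",
                  nm, min(rr), max(rr), residue_span[1], residue_span[2])
    }
  }
  sc
}

required_regions <- function() {
  c("JMR", "JM-B", "JM-S", "JM-Z", "N-lobe", "C-lobe",
    "A-loop", "C-loop", "Ca-helix", "P-loop", "KID")
}

#' @rdname region_scheme
#' @param scheme a `RegionScheme`.
#' @param name region name.
#' @return `region_residues()`: integer vector of residue numbers in the region.
#' @export
region_residues <- function(scheme, name) {
  m <- scheme$regions[[name]]
  if (is.null(m))
    trj_error("trajcomm_scheme_error", "region not defined: %s", name)
  sort(unique(unlist(apply(m, 1, function(r) r[1]:r[2], simplify = FALSE))))
}

#' Default CSF-1R cytoplasmic-region scheme
#'
#' Author numbering of the modeled cytoplasmic region (residues 543-922).
#' `variant = "trajectory"` defines JMR as 543-580 (the modeled construct
#' starts at 543); `variant = "sequence"` keeps the sequence-analysis
#' definition 538-580. The JM-Z range is not printed anywhere authoritative
#' and defaults to the JMR remainder 565-580; override via `jm_z`.
#'
#' @param variant `"trajectory"` or `"sequence"`.
#' @param jm_z inclusive JM-Z range.
#' @return `RegionScheme`.
#' @export
csf1r_region_scheme <- function(variant = c("trajectory", "sequence"),
                                jm_z = c(565L, 580L)) {
  variant <- match.arg(variant)
  jmr_lo <- if (variant == "trajectory") 543L else 538L
  region_scheme(list(
    "JMR" = c(jmr_lo, 580L),
    "JM-B" = c(543L, 552L),
    "JM-S" = c(553L, 564L),
    "JM-Z" = jm_z,
    "N-lobe" = c(582L, 664L),
    "C-lobe" = c(671L, 922L),
    "A-loop" = c(796L, 825L),
    "C-loop" = c(773L, 783L),
    "Ca-helix" = c(625L, 645L),
    "P-loop" = c(589L, 596L),
    "KID" = c(678L, 692L)
  ))
}

#' Toy region scheme for synthetic chains
#'
#' Maps all required region names proportionally onto a chain numbered
#' `1..n_residues` so the full pipeline runs on synthetic fixtures.
#'
#' @param n_residues chain length (>= 40).
#' @return `RegionScheme`.
#' @export
toy_region_scheme <- function(n_residues) {
  stopifnot(n_residues >= 40)
  f <- function(a, b) c(max(1L, round(a * n_residues)), round(b * n_residues))
  region_scheme(list(
    "JMR" = f(0.001, 0.20),
    "JM-B" = f(0.001, 0.10),
    "JM-S" = f(0.11, 0.16),
    "JM-Z" = f(0.17, 0.20),
    "N-lobe" = f(0.22, 0.50),
    "P-loop" = f(0.23, 0.28),
    "Ca-helix" = f(0.32, 0.40),
    "C-lobe" = f(0.52, 1.00),
    "C-loop" = f(0.55, 0.62),
    "A-loop" = f(0.66, 0.80),
    "KID" = f(0.85, 0.92)
  ), residue_span = c(1L, as.integer(n_residues)))
}
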