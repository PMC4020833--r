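#' Run configuration
#'
#' A single configuration drives both variants of a comparison so that all
#' thresholds are guaranteed identical across native and mutant. Serialized
#' as JSON; `read_run_config()`/`write_run_config()` round-trip unchanged.
#'
#' @param variants named list, one entry per variant; each is either
#'   `list(structure = path, trajectories = c(paths))` for on-disk inputs or
#'   `list(simulate = list(...))` with [planted_spec()] arguments plus
#'   `n_frames`, `n_replicas`, `geometry`.
#' @param scheme `"toy"` (with `scheme_n_residues`) or `"csf1r"`.
#' @param scheme_n_residues chain length for the toy scheme.
#' @param thresholds named list; defaults:
#'   `r` 0.1 nm (convergence), `d_cut` 3.6 A, `contact_dist` 4.0 A,
#'   `persistence` 0.5, `keep_fraction` 0.01, `ct_cut` NA (auto),
#'   `target_fraction` 0.1, `hbond_dist` 3.5 A, `hbond_angle` 120 deg,
#'   `variance_fraction` 0.8, `stride_d_ps` 10, `stride_hbond_ps` 100,
#'   `discard_head_ns` 0, `hub_degree` 5.
#' @param seeds `list(simulate = , convergence = )`.
#' @param outdir output directory.
#' @return object of class `RunConfig`.
#' @export
run_config <- function(variants, scheme = "toy", scheme_n_residues = 60,
                       thresholds = list(), seeds = list(), outdir = tempfile("trajcomm_run_")) {
  def <- list(r = 0.1, d_cut = 3.6, contact_dist = 4.0, persistence = 0.5,
              keep_fraction = 0.01, ct_cut = NA, target_fraction = 0.1,
              hbond_dist = 3.5, hbond_angle = 120, variance_fraction = 0.8,
              stride_d_ps = 10, stride_hbond_ps = 100, discard_head_ns = 0,
              hub_degree = 5)
  thresholds <- thresholds[!vapply(thresholds, is.null, logical(1))]
  thr <- utils::modifyList(def, thresholds)
  thr <- thr[c(names(def), setdiff(names(thr), names(def)))]
  for (nm in setdiff(names(thr), "ct_cut"))
    if (!is.na(thr[[nm]]) && thr[[nm]] <= 0 && nm != "discard_head_ns")
      trj_error("trajcomm_argument_error", "threshold %s must be positive", nm)
  sd <- utils::modifyList(list(simulate = 1L, convergence = 1L), seeds)
  structure(list(variants = variants, scheme = scheme,
                 scheme_n_residues = scheme_n_residues, thresholds = thr,
                 seeds = sd, outdir = outdir),
            class = "RunConfig")
}

#' @rdname run_config
#' @param config a `RunConfig`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  o$variants <- lapply(o$variants, function(v) {
    if (!is.null(v$simulate)) {
      v$simulate <- as.list(v$simulate)
      cb <- v$simulate$cluster_blocks
      if (is.data.frame(cb)) # simplifyVector collapses the list of blocks
        v$simulate$cluster_blocks <- lapply(seq_len(nrow(cb)), function(i)
          list(range = unlist(cb$range[i]), rho = cb$rho[i], sigma = cb$sigma[i]))
    }
    v
  })
  run_config(o$variants, o$scheme, o$scheme_n_residues,
             as.list(o$thresholds), as.list(o$seeds), o$outdir)
}

config_scheme <- function(config) {
  switch(config$scheme,
    toy = toy_region_scheme(config$scheme_n_residues),
    csf1r = csf1r_region_scheme(),
    trj_error("trajcomm_argument_error", "unknown scheme '%s'", config$scheme))
}

# materialize (structure, ensemble) for one variant
variant_inputs <- function(vcfg, config) {
  if (!is.null(vcfg$simulate)) {
    s <- vcfg$simulate
    structure <- make_toy_structure(s$n_residues %||% config$scheme_n_residues,
                                    s$geometry %||% "helix", TRUE)
    blocks <- s$cluster_blocks %||% list()
    if (is.data.frame(blocks))
      blocks <- lapply(seq_len(nrow(blocks)), function(i)
        list(range = unlist(blocks$range[i]), rho = blocks$rho[i], sigma = blocks$sigma[i]))
    spec <- planted_spec(s$n_residues %||% config$scheme_n_residues,
                         cluster_blocks = blocks,
                         background_sigma = s$background_sigma %||% 0.05,
                         replica_drift = s$replica_drift,
                         seed = s$seed %||% config$seeds$simulate)
    ens <- sample_ensemble(structure, spec, s$n_frames %||% 200,
                           s$n_replicas %||% 2)
  } else {
    structure <- load_structure(vcfg$structure,
                                vcfg$dialect %||% "pdb")
    ens <- load_trajectory(vcfg$trajectories, structure,
                           stride_ps = vcfg$stride_ps %||% 1)
  }
  list(structure = structure, ens = ens)
}

write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage per variant on the merged trajectory -- regional
#' RMSD/RMSF, d1/d2 distance series, H-bond occupancy over the canonical
#' region pairs, Calpha PCA spectrum, collectivity of the leading modes over
#' the juxtamembrane region, convergence scan, communication network with
#' summary -- plus the 10 x 10 mode-overlap grid between the two variants.
#' Every artifact is listed in `manifest.json` together with the md5 of the
#' serialized configuration; rerunning with the same seeds is byte-identical.
#'
#' @param config `RunConfig`.
#' @return invisible list of per-variant bundles (structure, ensemble,
#'   results, file paths) plus `manifest`.
#' @export
run_pipeline <- function(config) {
  scheme <- config_scheme(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  thr <- config$thresholds
  files <- character(0)
  bundles <- list()
  cfg_path <- file.path(config$outdir, "config.json")
  write_run_config(config, cfg_path)
  files <- c(files, cfg_path)

  for (vn in names(config$variants)) {
    inp <- tryCatch(variant_inputs(config$variants[[vn]], config),
                    error = function(e) stop("stage input [", vn, "]: ",
                                             conditionMessage(e), call. = FALSE))
    st <- inp$structure
    # fail fast on scheme/structure mismatch before any heavy compute
    for (nm in required_regions()) {
      rr <- region_residues(scheme, nm)
      if (!any(rr %in% st$atoms$residue_number))
        trj_error("trajcomm_scheme_error",
                  "region %s has no atoms in variant %s", nm, vn)
    }
    merged <- merge_replicas(inp$ens, thr$discard_head_ns)
    res <- list()
    stage <- function(name, expr) {
      tryCatch(expr, error = function(e)
        stop("stage ", name, " [", vn, "]: ", conditionMessage(e), call. = FALSE))
    }
    res$rmsd <- stage("geometry", {
      out <- lapply(c("JMR", "N-lobe", "C-lobe", "A-loop"), function(rg)
        regional_rmsd(merged, st, scheme, rg, "N-lobe"))
      names(out) <- c("JMR", "N-lobe", "C-lobe", "A-loop")
      out
    })
    res$rmsf <- stage("geometry", rmsf(merged, st, "backbone", "residue"))
    res$d1 <- stage("geometry", centroid_distance(merged, st, scheme, "d1", thr$stride_d_ps))
    res$d2 <- stage("geometry", centroid_distance(merged, st, scheme, "d2", thr$stride_d_ps))
    hb_pairs <- canonical_hbond_pairs(scheme)
    res$hbonds <- stage("geometry",
      hbond_occupancy(merged, st, hb_pairs, thr$stride_hbond_ps,
                      thr$hbond_dist, thr$hbond_angle))
    res$pca <- stage("modes", pca_modes(merged, st, "backbone", 10))
    jmr_atoms <- select_atoms(st, "backbone", region_residues(scheme, "JMR"))
    res$collectivity <- stage("modes", vapply(seq_len(min(10, length(res$pca$values))),
      function(k) collectivity(res$pca, k, jmr_atoms), numeric(1)))
    res$convergence <- stage("convergence",
      convergence_scan(merged, st, thr$r, 5, config$seeds$convergence))
    res$network <- stage("network",
      communication_network(merged, st, thr$variance_fraction, thr$d_cut,
                            thr$contact_dist, thr$persistence, thr$keep_fraction,
                            if (is.na(thr$ct_cut)) NULL else thr$ct_cut,
                            thr$target_fraction, thr$hub_degree))
    res$summary <- stage("network", network_summary(res$network, scheme))

    vd <- file.path(config$outdir, vn)
    dir.create(vd, showWarnings = FALSE)
    files <- c(files,
      write_table(data.frame(time_ps = flat_times(merged),
                             as.data.frame(res$rmsd, check.names = FALSE)),
                  file.path(vd, "rmsd.csv")),
      write_table(data.frame(residue = as.integer(names(res$rmsf)),
                             rmsf_nm = unname(res$rmsf)),
                  file.path(vd, "rmsf.csv")),
      write_table(data.frame(time_ns = res$d1$times / 1000, d1_nm = res$d1$values,
                             d2_nm = res$d2$values),
                  file.path(vd, "distances.csv")),
      write_table(do.call(rbind, lapply(res$hbonds, function(h)
                    data.frame(contact = sprintf("%d...%d", h$res_a, h$res_b),
                               occupancy_pct = h$occupancy))),
                  file.path(vd, "hbond_occupancy.csv")),
      write_table(data.frame(mode = seq_along(res$pca$values),
                             eigenvalue_nm2 = res$pca$values),
                  file.path(vd, "pca_spectrum.csv")),
      write_table(data.frame(mode = seq_along(res$collectivity),
                             kappa_JMR = res$collectivity),
                  file.path(vd, "collectivity.csv")),
      write_table(as.data.frame(res$convergence$reports[[res$convergence$chosen]]$populations),
                  file.path(vd, "convergence_populations.csv")))
    conv_path <- file.path(vd, "convergence.json")
    ch <- res$convergence$reports[[res$convergence$chosen]]
    jsonlite::write_json(list(chosen_run = res$convergence$chosen,
                              r_nm = ch$r,
                              n_references = nrow(ch$references),
                              lone_references = length(ch$lone_references),
                              balance = ch$balance),
                         conv_path, digits = NA, auto_unbox = TRUE)
    files <- c(files, conv_path)
    net_path <- file.path(vd, "network.graphml")
    write_network_graphml(res$network, net_path, scheme)
    sum_path <- write_table(res$summary$region_pair_counts,
                            file.path(vd, "network_summary.csv"))
    prov_path <- file.path(vd, "provenance.json")
    jsonlite::write_json(list(variant = vn, p_cut = res$network$p_cut,
                              ct_cut = res$network$ct_cut,
                              retained_modes = res$network$retained_modes,
                              n_ids = length(res$network$ids),
                              n_cps = length(res$network$cps),
                              pairwise_paths = res$summary$pairwise_paths,
                              hubs = res$summary$hubs),
                         prov_path, digits = NA, auto_unbox = TRUE)
    files <- c(files, net_path, sum_path, prov_path)
    bundles[[vn]] <- list(structure = st, ensemble = merged, results = res,
                          scheme = scheme)
  }

  if (length(bundles) >= 2) {
    a <- bundles[[1]]$results$pca; b <- bundles[[2]]$results$pca
    k <- min(10, ncol(a$vectors), ncol(b$vectors))
    grid <- (crossprod(a$vectors[, seq_len(k), drop = FALSE],
                       b$vectors[, seq_len(k), drop = FALSE]))^2
    gp <- file.path(config$outdir, "overlap_grid.csv")
    utils::write.csv(round(grid, 10), gp, quote = FALSE)
    files <- c(files, gp)
  }
  mp <- file.path(config$outdir, "manifest.json")
  manifest <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                   files = sort(c(files, mp)))
  jsonlite::write_json(manifest, mp, digits = NA, auto_unbox = TRUE)
  bundles$manifest <- manifest
  invisible(bundles)
}

# residue-level pairs to monitor for H-bond occupancy: nearest canonical
# region pairs (JM-B vs Ca-helix, JM-S vs C-loop, A-loop vs C-loop)
canonical_hbond_pairs <- function(scheme) {
  mk <- function(a, b) c(region_residues(scheme, a)[1], region_residues(scheme, b)[1])
  list(mk("JM-B", "Ca-helix"), mk("JM-S", "C-loop"), mk("A-loop", "C-loop"))
}

#' Compare two variant bundles
#'
#' Mirrors the native-vs-mutant contrasts: per-contact occupancy differences
#' and fold changes, eigenvalue ratios of the first 10 modes, region-pair CP
#' count differences, and IDS matching by residue overlap (Jaccard).
#'
#' @param bundleA,bundleB elements of the [run_pipeline()] return value.
#' @return list with `occupancy`, `eigenvalue_ratio`, `region_pair_delta`,
#'   `ids_match`.
#' @export
compare_variants <- function(bundleA, bundleB) {
  if (!identical(bundleA$scheme$regions, bundleB$scheme$regions))
    trj_error("trajcomm_comparison_error", "bundles use different region schemes")
  occ <- do.call(rbind, Map(function(a, b) {
    data.frame(contact = sprintf("%d...%d", a$res_a, a$res_b),
               occ_a = a$occupancy, occ_b = b$occupancy,
               delta = a$occupancy - b$occupancy,
               fold = ifelse(b$occupancy > 0, a$occupancy / b$occupancy, Inf))
  }, bundleA$results$hbonds, bundleB$results$hbonds))
  k <- min(10, length(bundleA$results$pca$values), length(bundleB$results$pca$values))
  ratio <- bundleA$results$pca$values[seq_len(k)] / bundleB$results$pca$values[seq_len(k)]
  rp <- merge(bundleA$results$summary$region_pair_counts,
              bundleB$results$summary$region_pair_counts,
              by = c("region_a", "region_b"), suffixes = c("_a", "_b"))
  rp$delta <- rp$paths_a - rp$paths_b
  ids_a <- bundleA$results$network$ids; ids_b <- bundleB$results$network$ids
  match_tab <- do.call(rbind, lapply(seq_along(ids_a), function(i) {
    ja <- vapply(ids_b, function(s)
      length(intersect(ids_a[[i]]$residues, s$residues)) /
      length(union(ids_a[[i]]$residues, s$residues)), numeric(1))
    best <- if (length(ja)) which.max(ja) else NA_integer_
    data.frame(ids_a = i, best_match_b = best,
               jaccard = if (length(ja)) max(ja) else 0)
  }))
  list(occupancy = occ, eigenvalue_ratio = ratio,
       region_pair_delta = rp, ids_match = match_tab)
}
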