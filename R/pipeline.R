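# Pipeline orchestration: run every analysis stage from one validated
# config, with deterministic seeding and a run manifest.

.pipeline_keys <- c("seed", "out_dir", "synthetic", "systems",
                    "frame_interval_ns", "discard_ns", "domain_map",
                    "pocket_residues", "helix", "pca", "msm",
                    "rigid_core", "redan", "hbond")

#' Validate a pipeline configuration
#'
#' @param config named list or path to a YAML file.
#' @return The validated config (invisible errors otherwise).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  unknown <- setdiff(names(config), .pipeline_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$seed)) stop("config key missing: seed")
  if (is.null(config$out_dir)) stop("config key missing: out_dir")
  if (is.null(config$synthetic)) {
    if (is.null(config$systems))
      stop("config key missing: systems (or synthetic)")
    if (is.null(config$domain_map))
      stop("config key missing: domain_map")
    if (is.null(config$frame_interval_ns))
      stop("config key missing: frame_interval_ns")
  }
  invisible(config)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline from a config
#'
#' Stages: input (synthetic generation or trajectory loading and
#' equilibration discard), features, PCA landscape, MSM + PCCA
#' kinetics, rigid core, REDAN pathway, and differential H-bond
#' network. Intermediate tables are written as TSV/JSON under
#' `out_dir` and listed in `manifest.json` together with the seed and
#' the effective parameters. All randomness derives from `config$seed`.
#'
#' @param config named list or YAML path; see `validate_config()` and
#'   the package vignette for the schema.
#' @return list with the main in-memory results and `manifest`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  outputs <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # ---- input stage -------------------------------------------------
  res <- stage("input", {
    if (!is.null(config$synthetic)) {
      args <- config$synthetic
      args$seed <- args$seed %||% config$seed
      spec <- do.call(synthetic_spec, args)
      gen <- generate_ensembles(spec)
      dmap <- spec$domain_map
      list(A = gen$A, B = gen$B, truth = gen$truth, dmap = dmap)
    } else {
      dmap <- domain_map(lapply(config$domain_map$domains, function(r)
        r[1]:r[2]),
        lapply(config$domain_map$elements %||% list(), function(r)
          r[1]:r[2]))
      load_one <- function(sy) {
        top <- load_topology(sy$pdb)
        ens <- load_ensemble(top, sy$trajectories,
                             config$frame_interval_ns,
                             stride = sy$stride %||% 1L,
                             unit = sy$unit %||% "angstrom",
                             system = sy$label)
        if (!is.null(config$discard_ns))
          ens <- discard_equilibration(ens, config$discard_ns)
        ens
      }
      list(A = load_one(config$systems[[1]]),
           B = load_one(config$systems[[2]]), truth = NULL, dmap = dmap)
    }
  })
  ens_a <- res$A; ens_b <- res$B; dmap <- res$dmap

  # ---- features ----------------------------------------------------
  pocket <- config$pocket_residues %||%
    tail(dmap$domains[[length(dmap$domains)]], 24)
  feats <- stage("features", {
    fa <- com_pair_distances(ens_a, pocket)
    fb <- com_pair_distances(ens_b, pocket)
    fc <- combine_features(fa, fb)
    outputs$features <- write_tsv(
      data.frame(fc$info, fc$values, check.names = FALSE),
      file.path(out_dir, "features_com_pairs.tsv"))
    fc
  })

  # ---- landscape ---------------------------------------------------
  land <- stage("pca", {
    model <- fit_pca(feats)
    proj <- project_pca(model, feats)
    tl <- top_loadings(model, k = min(10, length(model$labels)))
    outputs$projection <- write_tsv(
      data.frame(feats$info, proj, check.names = FALSE),
      file.path(out_dir, "pca_projection.tsv"))
    outputs$top_loadings <- write_tsv(
      tl$combined, file.path(out_dir, "pca_top_loadings.tsv"))
    list(model = model, proj = proj)
  })

  # ---- kinetics ----------------------------------------------------
  msm_cfg <- config$msm %||% list()
  kin <- stage("msm", {
    n_micro <- msm_cfg$n_micro %||% 300
    lags <- msm_cfg$lags %||% c(1, 2, 5, 10, 20)
    lag <- msm_cfg$lag %||% 5
    n_macro <- msm_cfg$n_macro %||% 5
    micro <- cluster_microstates(land$proj, n_micro = n_micro,
                                 max_fit_frames =
                                   msm_cfg$max_fit_frames %||% 5000)
    traj <- paste(feats$info$system, feats$info$replica, sep = "/")
    its <- implied_timescales(micro$labels, lags, traj,
                              dt_ns = ens_a$dt_ns)
    C <- count_transitions(micro$labels, lag, traj)
    tm <- transition_matrix(C, lag_frames = lag,
                            lag_ns = lag * ens_a$dt_ns)
    macro <- pcca_coarse_grain(tm, n_macro, microstates = micro,
                               system = feats$info$system)
    outputs$implied_timescales <- write_tsv(
      its, file.path(out_dir, "implied_timescales.tsv"))
    outputs$occupancy <- write_tsv(
      data.frame(system = rownames(macro$occupancy), macro$occupancy,
                 check.names = FALSE),
      file.path(out_dir, "macrostate_occupancy.tsv"))
    list(micro = micro, tm = tm, macro = macro)
  })
  macro_labels <- kin$macro$frame_labels

  # ---- rigid core --------------------------------------------------
  rc_cfg <- config$rigid_core %||% list()
  rigid <- stage("rigidcore", {
    dn <- names(dmap$domains)
    d1 <- rc_cfg$domain1 %||% dn[1]
    d2 <- rc_cfg$domain2 %||% dn[2]
    pairs <- select_interdomain_ca_pairs(
      ens_a, ens_b, domain_residues(dmap, d1), domain_residues(dmap, d2),
      cutoff = rc_cfg$cutoff %||% 10, stride = rc_cfg$stride %||% 10)
    if (!nrow(pairs)) {
      outputs$rigid_core <- write_tsv(
        data.frame(note = "no inter-domain pairs within the cutoff"),
        file.path(out_dir, "rigid_core.tsv"))
      list(pairs = pairs, table = NULL, selection = NULL)
    } else {
      fm <- combine_features(ca_pair_distances(ens_a, pairs),
                             ca_pair_distances(ens_b, pairs))
      tab <- pair_variability(fm)
      sel <- rigid_core_selection(tab, min(rc_cfg$k %||% 200, nrow(tab)))
      outputs$rigid_core <- write_tsv(
        sel, file.path(out_dir, "rigid_core.tsv"))
      list(pairs = pairs, table = tab, selection = sel)
    }
  })

  # ---- REDAN -------------------------------------------------------
  rd_cfg <- config$redan %||% list()
  redan <- stage("redan", {
    g <- build_pre_graph(ens_a, ens_b,
                         residues = rd_cfg$residues,
                         cutoff = rd_cfg$cutoff %||% 10,
                         bin_width = rd_cfg$bin_width %||% 0.1,
                         stride = rd_cfg$stride %||% 1L)
    outputs$pre_edges <- write_tsv(
      g$edges, file.path(out_dir, "pre_edges.tsv"))
    paths <- NULL
    if (!is.null(rd_cfg$source) && !is.null(rd_cfg$target)) {
      paths <- lapply(rd_cfg$target, function(t)
        shortest_allosteric_path(g, rd_cfg$source, t)[[1]])
      jsonlite::write_json(
        lapply(paths, function(p) list(residues = p$residues,
                                       total_weight = p$total_weight)),
        file.path(out_dir, "allosteric_paths.json"), auto_unbox = TRUE,
        digits = NA)
      outputs$paths <- file.path(out_dir, "allosteric_paths.json")
    }
    list(graph = g, paths = paths)
  })

  # ---- H-bond network ---------------------------------------------
  hb_cfg <- config$hbond %||% list()
  hbond <- stage("hbond", {
    rec <- combine_hbonds(
      detect_hbonds(ens_a, min_freq = hb_cfg$min_freq %||% 0.1),
      detect_hbonds(ens_b, min_freq = hb_cfg$min_freq %||% 0.1))
    rates <- hbond_rates_by_state(rec, macro_labels)
    ref <- hb_cfg$ref_state %||% 1
    diffnet <- differential_hbond_network(
      rates, ref, up = hb_cfg$up %||% 1.5, down = hb_cfg$down %||% 0.5,
      min_rate = hb_cfg$min_rate %||% 0.05)
    cons <- conserved_hbonds(rates, floor = hb_cfg$floor %||% 0.5)
    outputs$hbond_rates <- write_tsv(
      data.frame(rec$bonds, rates, check.names = FALSE),
      file.path(out_dir, "hbond_rates.tsv"))
    outputs$hbond_differential <- write_tsv(
      rbind(cbind(direction = "gained", diffnet$gained),
            cbind(direction = "lost", diffnet$lost)),
      file.path(out_dir, "hbond_differential.tsv"))
    list(records = rec, rates = rates, differential = diffnet,
         conserved = cons)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("allopath")),
    seed = config$seed,
    n_frames = list(A = n_frames(ens_a), B = n_frames(ens_b)),
    parameters = config[setdiff(names(config), c("out_dir"))],
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(list(ensembles = list(A = ens_a, B = ens_b),
                 truth = res$truth, features = feats,
                 landscape = land, kinetics = kin, rigid_core = rigid,
                 redan = redan, hbond = hbond, manifest = manifest))
}
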