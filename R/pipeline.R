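#' Assemble and validate a pipeline run configuration
#'
#' Either pass a YAML file path or the fields directly. Paths point to the
#' on-disk input formats written by [write_fixture()]; all tunables carry
#' the pipeline defaults and round-trip losslessly through YAML.
#'
#' @param path optional YAML file with the fields below.
#' @param network,expression,phenotypes,markers paths to the input files.
#' @param mutations optional mutation file path (gene, effect).
#' @param out_dir output directory.
#' @param alpha,tolerance,max_iterations see [sfa_config()].
#' @param n_random random initial states (default 100000).
#' @param k_range candidate cluster counts (default 2:10).
#' @param threshold criterion-2 marker fraction (default 0.9).
#' @param mode criterion-2 mode, `"strict"` (default) or `"relaxed"`.
#' @param scheme_cap control-node cap for scheme generation.
#' @param seed master RNG seed.
#' @return a `run_config` list.
#' @export
run_config <- function(path = NULL, network = NULL, expression = NULL,
                       phenotypes = NULL, markers = NULL, mutations = NULL,
                       out_dir = "fvscreen_out", alpha = 0.9,
                       tolerance = 1e-6, max_iterations = 1000L,
                       n_random = 100000L, k_range = 2:10, threshold = 0.9,
                       mode = "strict", scheme_cap = 16L, seed = 1L) {
  cfg <- list(network = network, expression = expression,
              phenotypes = phenotypes, markers = markers,
              mutations = mutations, out_dir = out_dir, alpha = alpha,
              tolerance = tolerance, max_iterations = max_iterations,
              n_random = n_random, k_range = k_range, threshold = threshold,
              mode = mode, scheme_cap = scheme_cap, seed = seed)
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    for (nm in names(y)) cfg[[nm]] <- y[[nm]]
  }
  for (nm in c("network", "expression", "phenotypes", "markers")) {
    if (is.null(cfg[[nm]])) stop("run_config: missing required field ", nm)
  }
  cfg$k_range <- as.integer(cfg$k_range)
  if (length(cfg$k_range) == 2 && is.null(path) == FALSE &&
      cfg$k_range[1] < cfg$k_range[2]) {
    # YAML writes ranges as two-element lists; re-expand
    cfg$k_range <- cfg$k_range[1]:cfg$k_range[2]
  }
  structure(cfg, class = "run_config")
}

#' Save a run configuration as YAML
#' @param cfg a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  u <- unclass(cfg)
  u$k_range <- range(u$k_range)
  yaml::write_yaml(u, path)
  invisible(path)
}

read_inputs <- function(cfg) {
  g <- read_network(cfg$network)
  expr <- read_expression(cfg$expression, cfg$phenotypes)
  mk <- utils::read.delim(cfg$markers, colClasses = "character")
  if (is.null(mk$direction)) mk$direction <- NA_character_
  if (is.null(mk$group)) mk$group <- "all"
  markers <- marker_spec(mk$node, mk$direction, mk$group)
  mut <- NULL
  if (!is.null(cfg$mutations) && nzchar(cfg$mutations) &&
      file.exists(cfg$mutations)) {
    mt <- utils::read.delim(cfg$mutations, colClasses = "character")
    mut <- mutation_profile(mt$gene, mt$effect)
  }
  list(g = g, expr = expr, markers = markers, mutations = mut)
}

#' Cross-check the pipeline inputs
#'
#' Verifies node names across network, expression, markers and mutations:
#' expression rows absent from the network are a warning (ignored
#' downstream), network nodes missing from the expression table, unknown
#' marker nodes, and unknown mutation genes are failures.
#'
#' @param cfg a `run_config`.
#' @return a validation report list with `ok`, `errors`, `warnings`,
#'   `counts`.
#' @export
validate_inputs <- function(cfg) {
  inp <- read_inputs(cfg)
  errors <- character()
  warns <- character()
  extra <- setdiff(rownames(inp$expr$values), inp$g$nodes)
  if (length(extra)) {
    warns <- c(warns, paste("expression rows not in the network (ignored):",
                            paste(extra, collapse = ", ")))
  }
  missing <- setdiff(inp$g$nodes, rownames(inp$expr$values))
  if (length(missing)) {
    errors <- c(errors, paste("network nodes missing from expression:",
                              paste(missing, collapse = ", ")))
  }
  badmk <- setdiff(inp$markers$node, inp$g$nodes)
  if (length(badmk)) {
    errors <- c(errors, paste("marker nodes not in the network:",
                              paste(badmk, collapse = ", ")))
  }
  if (!is.null(inp$mutations)) {
    badmu <- setdiff(inp$mutations$gene, inp$g$nodes)
    if (length(badmu)) {
      errors <- c(errors, paste("mutation genes not in the network:",
                                paste(badmu, collapse = ", ")))
    }
  }
  if (!any(inp$expr$phenotype == "undesired") ||
      !any(inp$expr$phenotype == "desired")) {
    errors <- c(errors,
                "both undesired and desired samples are required")
  }
  list(ok = length(errors) == 0, errors = errors, warnings = warns,
       counts = list(nodes = length(inp$g$nodes),
                     edges = nrow(inp$g$edges),
                     samples = ncol(inp$expr$values),
                     markers = nrow(inp$markers)))
}

manifest_path <- function(out_dir, step) {
  file.path(out_dir, "checkpoints", paste0(step, ".json"))
}

step_manifest <- function(cfg, step, inputs_hash) {
  list(step = step, inputs = inputs_hash, seed = cfg$seed,
       alpha = cfg$alpha, n_random = cfg$n_random,
       threshold = cfg$threshold, mode = cfg$mode)
}

config_hash <- function(cfg) {
  files <- unlist(cfg[c("network", "expression", "phenotypes", "markers",
                        "mutations")])
  files <- files[!is.na(files) & nzchar(files) & file.exists(files)]
  as.list(tools::md5sum(files))
}

checkpoint_fresh <- function(out_dir, step, manifest, outputs) {
  mp <- manifest_path(out_dir, step)
  if (!file.exists(mp) || !all(file.exists(file.path(out_dir, outputs)))) {
    return(FALSE)
  }
  old <- jsonlite::read_json(mp, simplifyVector = TRUE)
  identical(jsonlite::toJSON(old, auto_unbox = TRUE),
            jsonlite::toJSON(manifest, auto_unbox = TRUE))
}

write_checkpoint <- function(out_dir, step, manifest) {
  dir.create(file.path(out_dir, "checkpoints"), showWarnings = FALSE,
             recursive = TRUE)
  jsonlite::write_json(manifest, manifest_path(out_dir, step),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run the full reprogramming-screen pipeline
#'
#' Executes the three stages in order: (1) attractor-landscape estimation
#' and clustering with marker consistency checks; (2) FVS identification
#' and the 3^n perturbation screen from the undesired replicates; (3) the
#' two filtering criteria and survivor ranking. Each stage writes TSV
#' outputs and a checkpoint manifest (input hashes + seeds) under
#' `out_dir`; on a re-run a stage whose manifest matches and whose outputs
#' exist is skipped, a stale manifest re-runs the stage with a notice.
#' A final `report.json` aggregates counts at every stage.
#'
#' @param cfg a `run_config`.
#' @param fvs optional pre-computed FVS member vector; default: the first
#'   minimal FVS found by [enumerate_fvs()].
#' @return the run report (invisibly also written as JSON): list of stage
#'   counts and the survivor table.
#' @export
run_pipeline <- function(cfg, fvs = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  val <- validate_inputs(cfg)
  if (!val$ok) stop("input validation failed:\n  ",
                    paste(val$errors, collapse = "\n  "))
  inp <- read_inputs(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  sfa <- sfa_config(cfg$alpha, cfg$tolerance, cfg$max_iterations)
  g <- inp$g
  expr <- align_expression(inp$expr, g)
  hash <- config_hash(cfg)

  state_file <- function(step) {
    file.path(cfg$out_dir, "checkpoints", paste0(step, "_state.rds"))
  }
  run_step <- function(step, manifest, outputs, compute) {
    sf <- state_file(step)
    if (checkpoint_fresh(cfg$out_dir, step, manifest,
                         c(outputs, file.path("checkpoints",
                                              basename(sf))))) {
      message("run_pipeline: '", step, "' checkpoint fresh, skipping")
      return(readRDS(sf))
    }
    if (file.exists(manifest_path(cfg$out_dir, step))) {
      message("run_pipeline: '", step,
              "' checkpoint stale (inputs or settings changed), re-running")
    }
    res <- compute()
    dir.create(file.path(cfg$out_dir, "checkpoints"), showWarnings = FALSE,
               recursive = TRUE)
    saveRDS(res, sf)
    write_checkpoint(cfg$out_dir, step, manifest)
    res
  }

  # -- step 1: landscape -----------------------------------------------
  base_ov <- baseline_override_set(g, undesired_values(expr),
                                   inp$mutations, NULL)
  s1 <- run_step("landscape", step_manifest(cfg, "landscape", hash),
                 c("attractors.tsv", "clusters.tsv"), function() {
    landscape <- build_landscape(g, expr, sfa, n_random = cfg$n_random,
                                 seed = cfg$seed,
                                 baseline_overrides = base_ov)
    model <- choose_k(landscape, k_range = cfg$k_range, seed = cfg$seed)
    consistency <- check_marker_consistency(landscape, inp$markers)
    write_attractors(landscape, file.path(cfg$out_dir, "attractors.tsv"))
    utils::write.table(
      data.frame(state = colnames(landscape$values)[model$kept],
                 cluster = model$assignment,
                 provenance = landscape$provenance[model$kept]),
      file.path(cfg$out_dir, "clusters.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    jsonlite::write_json(
      list(k = model$k, k_elbow = model$k_elbow,
           k_silhouette = model$k_silhouette, rationale = model$rationale,
           wcss = as.list(model$wcss),
           silhouette = as.list(model$silhouette),
           random_state_distribution = "uniform within pooled ranges"),
      file.path(cfg$out_dir, "k_selection.json"), auto_unbox = TRUE,
      pretty = TRUE)
    list(landscape = landscape, model = model, consistency = consistency)
  })
  landscape <- s1$landscape
  model <- s1$model
  consistency <- s1$consistency

  # -- step 2: FVS + screen --------------------------------------------
  s2 <- run_step("screen", step_manifest(cfg, "screen", hash),
                 "scheme_manifest.tsv", function() {
    enum <- NULL
    if (is.null(fvs)) {
      enum <- enumerate_fvs(g, sa_schedule(seed = cfg$seed))
      fvs <- enum$fvs[[1]]
      utils::write.table(
        data.frame(members = vapply(enum$fvs, paste, "", collapse = ","),
                   size = enum$size, method = enum$method),
        file.path(cfg$out_dir, "fvs.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    }
    control <- exclude_fixed_nodes(fvs, names(base_ov))
    schemes <- generate_schemes(control, cap = cfg$scheme_cap)
    screen <- run_screen(g, schemes, expr, sfa, mutations = inp$mutations)
    utils::write.table(
      data.frame(scheme_id = screen$scheme_ids,
                 n_perturbed = rowSums(schemes$assignment != 0L)),
      file.path(cfg$out_dir, "scheme_manifest.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    for (r in screen$replicates) {
      write_attractors(
        list(values = screen$values[[r]], converged = screen$converged[[r]],
             iterations = screen$iterations[[r]]),
        file.path(cfg$out_dir, paste0("screen_attractors_", r, ".tsv")))
    }
    list(enum = enum, fvs = fvs, control = control, schemes = schemes,
         screen = screen)
  })
  enum <- s2$enum
  control <- s2$control
  schemes <- s2$schemes
  screen <- s2$screen
  fvs <- s2$fvs

  # -- step 3: filters --------------------------------------------------
  s3 <- run_step("filter", step_manifest(cfg, "filter", hash),
                 "survivors_ranked.tsv", function() {
    clfs <- train_classifiers(landscape, model, seed = cfg$seed)
    c1 <- criterion1(clfs, screen, model$desired_clusters)
    prov <- landscape$provenance[model$kept]
    phen <- landscape$phenotype[model$kept]
    vals <- landscape$values[, model$kept, drop = FALSE]
    c2 <- criterion2(screen, inp$markers,
                     vals[, prov == "experimental" & phen == "desired",
                          drop = FALSE],
                     vals[, prov == "experimental" & phen == "undesired",
                          drop = FALSE],
                     threshold = cfg$threshold, mode = cfg$mode)
    fi <- feature_importance(clfs, seed = cfg$seed)
    report <- summarize_survivors(screen, c1, c2)
    utils::write.table(
      data.frame(scheme_id = names(c1$verdict), pass = c1$verdict),
      file.path(cfg$out_dir, "criterion1_pass.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    for (r in screen$replicates) {
      utils::write.table(
        data.frame(scheme_id = c2$scheme_ids, pass = c2$per_replicate[, r],
                   min_group_fraction = c2$fractions[, r]),
        file.path(cfg$out_dir, paste0("criterion2_pass_", r, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(fi$importance,
                       file.path(cfg$out_dir, "feature_importance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(report$survivors,
                       file.path(cfg$out_dir, "survivors_ranked.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(clfs = clfs, c1 = c1, c2 = c2, report = report)
  })
  clfs <- s3$clfs
  c1 <- s3$c1
  c2 <- s3$c2
  report <- s3$report

  out <- list(
    nodes = length(g$nodes), edges = nrow(g$edges),
    samples = ncol(expr$values),
    attractors = ncol(landscape$values),
    non_converged = landscape$n_excluded,
    k = model$k,
    marker_consistency = consistency,
    n_fvs = if (!is.null(enum)) length(enum$fvs) else NA_integer_,
    fvs_size = length(fvs), control_nodes = control,
    schemes = nrow(schemes$assignment),
    criterion1_survivors = report$n_pass_c1,
    criterion2_survivors_per_replicate =
      as.list(colSums(c2$per_replicate)),
    survivors = report$survivors,
    training_accuracy = as.list(clfs$training_accuracy),
    seed = cfg$seed
  )
  json <- out
  json$marker_consistency <- NULL
  json$survivors <- report$survivors$scheme_id
  jsonlite::write_json(json, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}

#' Planted-scheme recovery under initial-state noise
#'
#' The fixture analogue of a noise-robustness study: for each trial, the
#' standard fixture's expression profiles are perturbed with Gaussian
#' noise of the given level, the landscape is re-estimated and
#' re-clustered, the classifiers retrained, the 3^n screen re-run, and
#' the filters applied. A trial counts as a recovery when the planted
#' scheme survives both criteria and the all-unchanged scheme does not.
#'
#' @param noise noise standard deviation (see [inject_noise()]).
#' @param n_trials number of seeded trials.
#' @param seed master seed; trial t uses `seed + t`.
#' @param n_random random landscape states per trial (small by design; the
#'   fixture network is 12 nodes).
#' @param mode criterion-2 mode.
#' @return list with `recovery_rate`, `recovered` (logical per trial),
#'   `planted_id`.
#' @export
robustness_recovery <- function(noise = 0.1, n_trials = 20L, seed = 1L,
                                n_random = 300L, mode = "strict") {
  fx <- standard_fixture(seed = seed)
  planted <- fx$planted_scheme
  recovered <- logical(n_trials)
  planted_id <- NULL
  for (t in seq_len(n_trials)) {
    s <- seed + t
    values <- inject_noise(fx$expr$values, noise, seed = s)
    expr <- expression_table(values, fx$expr$phenotype)
    res <- tryCatch(
      screen_and_filter(fx$g, expr, fx$markers, control = fx$control,
                        n_random = n_random, seed = s, mode = mode),
      error = function(e) NULL)
    if (is.null(res)) next
    planted_id <- scheme_ids(res$schemes)[apply(
      res$schemes$assignment, 1, function(a) {
        all(a[names(planted)] == planted) && sum(a != 0) == length(planted)
      })]
    unchanged_id <- scheme_ids(res$schemes)[1]
    surv <- res$report$survivors$scheme_id
    recovered[t] <- planted_id %in% surv && !(unchanged_id %in% surv)
  }
  list(recovery_rate = mean(recovered), recovered = recovered,
       planted_id = planted_id)
}

#' One-shot screen and filter on in-memory objects
#'
#' Convenience wrapper used by tests and the robustness harness: builds
#' the landscape, clusters it, trains the classifiers, screens all schemes
#' over the given control nodes, and applies both criteria.
#'
#' @param g a [signed_digraph].
#' @param expr an [expression_table].
#' @param markers a [marker_spec()].
#' @param control control-node vector (default: first minimal FVS).
#' @param n_random random landscape states.
#' @param seed RNG seed.
#' @param threshold,mode criterion-2 settings.
#' @param k_range candidate cluster counts.
#' @param cfg an [sfa_config()].
#' @param ntree random-forest size.
#' @return list with `landscape`, `model`, `clfs`, `schemes`, `screen`,
#'   `c1`, `c2`, `report`.
#' @export
screen_and_filter <- function(g, expr, markers, control = NULL,
                              n_random = 1000L, seed = 1L, threshold = 0.9,
                              mode = "strict", k_range = 2:6,
                              cfg = sfa_config(), ntree = 200L) {
  expr <- align_expression(expr, g)
  if (is.null(control)) {
    control <- enumerate_fvs(g, sa_schedule(seed = seed))$fvs[[1]]
  }
  landscape <- build_landscape(g, expr, cfg, n_random = n_random,
                               seed = seed)
  model <- choose_k(landscape, k_range = k_range, seed = seed)
  clfs <- train_classifiers(landscape, model, seed = seed, ntree = ntree)
  schemes <- generate_schemes(control)
  screen <- run_screen(g, schemes, expr, cfg)
  c1 <- criterion1(clfs, screen, model$desired_clusters)
  prov <- landscape$provenance[model$kept]
  phen <- landscape$phenotype[model$kept]
  vals <- landscape$values[, model$kept, drop = FALSE]
  c2 <- criterion2(screen, markers,
                   vals[, prov == "experimental" & phen == "desired",
                        drop = FALSE],
                   vals[, prov == "experimental" & phen == "undesired",
                        drop = FALSE],
                   threshold = threshold, mode = mode)
  report <- summarize_survivors(screen, c1, c2)
  list(landscape = landscape, model = model, clfs = clfs, schemes = schemes,
       screen = screen, c1 = c1, c2 = c2, report = report)
}
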