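#' Train the three landscape classifiers
#'
#' Fits Naive Bayes, a linear-kernel Support Vector Machine, and a Random
#' Forest to predict cluster membership from full attractor vectors (every
#' network node is a feature). Training data are the converged landscape
#' attractors and their k-means cluster labels; training accuracy is
#' recorded per classifier. The linear SVM kernel makes coefficient-based
#' feature importance well defined.
#'
#' @param landscape an `attractor_landscape`.
#' @param model a `cluster_model` from [choose_k()].
#' @param seed RNG seed (fixed before each fit).
#' @param ntree random-forest size (default 500).
#' @return an `attractor_classifiers` object: list with `nb`, `svm`, `rf`,
#'   `training_accuracy`, `features`, `levels`, and the training data
#'   (`x`, `y`) used for permutation importance.
#' @export
train_classifiers <- function(landscape, model, seed = 1L, ntree = 500L) {
  stopifnot(inherits(landscape, "attractor_landscape"),
            inherits(model, "cluster_model"))
  X <- t(landscape$values[, model$kept, drop = FALSE])
  y <- factor(model$assignment)
  if (nlevels(y) < 2) stop("classifier training requires >= 2 clusters")
  df <- as.data.frame(X)
  nb <- local_seed(seed, e1071::naiveBayes(df, y))
  sv <- local_seed(seed, e1071::svm(df, y, kernel = "linear", scale = FALSE))
  rf <- local_seed(seed,
                   randomForest::randomForest(df, y, ntree = ntree,
                                              importance = FALSE))
  acc <- c(
    naive_bayes = mean(stats::predict(nb, df) == y),
    svm = mean(stats::predict(sv, df) == y),
    random_forest = mean(stats::predict(rf, df) == y)
  )
  structure(list(nb = nb, svm = sv, rf = rf, training_accuracy = acc,
                 features = colnames(df), levels = levels(y),
                 x = df, y = y, seed = seed),
            class = "attractor_classifiers")
}

#' @export
print.attractor_classifiers <- function(x, ...) {
  cat("attractor_classifiers on", length(x$features), "features,",
      length(x$levels), "clusters; training accuracy:",
      paste(names(x$training_accuracy),
            sprintf("%.3f", x$training_accuracy), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

classifier_votes <- function(clfs, X) {
  df <- as.data.frame(X)[, clfs$features, drop = FALSE]
  data.frame(
    naive_bayes = as.character(stats::predict(clfs$nb, df)),
    svm = as.character(stats::predict(clfs$svm, df)),
    random_forest = as.character(stats::predict(clfs$rf, df)),
    stringsAsFactors = FALSE
  )
}

#' Filtering criterion 1: majority-vote classification to the desired cluster
#'
#' Each screen attractor is classified by the three trained algorithms; it
#' passes on a replicate iff at least 2 of 3 assign it to a desired-
#' phenotype cluster. A scheme's overall criterion-1 verdict requires a
#' pass on every replicate.
#'
#' @param clfs an `attractor_classifiers`.
#' @param screen a `screen_result`.
#' @param desired_clusters integer cluster ids associated with the desired
#'   phenotype (e.g. `model$desired_clusters`).
#' @return list with `votes` (data frame: replicate, scheme_id, the three
#'   predictions, n_desired, pass), `per_replicate` (logical matrix schemes
#'   x replicates), `verdict` (named logical per scheme, all-replicates
#'   rule).
#' @export
criterion1 <- function(clfs, screen, desired_clusters) {
  stopifnot(inherits(clfs, "attractor_classifiers"),
            inherits(screen, "screen_result"))
  desired <- as.character(desired_clusters)
  m <- length(screen$scheme_ids)
  per_rep <- matrix(NA, m, length(screen$replicates),
                    dimnames = list(NULL, screen$replicates))
  votes <- vector("list", length(screen$replicates))
  for (r in seq_along(screen$replicates)) {
    v <- classifier_votes(clfs, t(screen$values[[r]]))
    nd <- rowSums(matrix(as.matrix(v) %in% desired, nrow = nrow(v)))
    per_rep[, r] <- nd >= 2 & screen$converged[[r]]
    votes[[r]] <- data.frame(replicate = screen$replicates[r],
                             scheme_id = screen$scheme_ids, v,
                             n_desired = nd, pass = per_rep[, r],
                             stringsAsFactors = FALSE)
  }
  verdict <- stats::setNames(rowSums(!per_rep) == 0, screen$scheme_ids)
  list(votes = do.call(rbind, votes), per_replicate = per_rep,
       verdict = verdict)
}

#' Feature importance of the three classifiers
#'
#' Random Forest: mean decrease in Gini impurity. Linear SVM: aggregate
#' absolute coefficient magnitude of the primal weight vectors across the
#' pairwise decision functions. Naive Bayes: seeded permutation importance
#' (mean training-accuracy drop over `n_permutations` shuffles per
#' feature). Each ranking is cut at the top `ceiling(top_frac * p)`
#' features; the overlap between the three top lists is summarized.
#'
#' @param clfs an `attractor_classifiers`.
#' @param top_frac fraction of ranked features to report (default 0.1).
#' @param n_permutations permutation repeats for Naive Bayes (default 10).
#' @param seed RNG seed for the permutations.
#' @return list with `importance` (data frame: feature, one column per
#'   classifier), `top` (list of top-feature character vectors per
#'   classifier), `top_n`, `overlap` (features in more than one top list;
#'   empty means the top lists are mutually exclusive).
#' @export
feature_importance <- function(clfs, top_frac = 0.1, n_permutations = 10L,
                               seed = 1L) {
  stopifnot(inherits(clfs, "attractor_classifiers"))
  p <- length(clfs$features)
  top_n <- ceiling(top_frac * p)

  rf_imp <- randomForest::importance(clfs$rf, type = 2)[, 1]
  rf_imp <- rf_imp[clfs$features]

  # primal weights per pairwise SVM: w = t(coefs) %*% SV
  Wsv <- crossprod(clfs$svm$coefs, as.matrix(clfs$svm$SV))
  sv_imp <- colSums(abs(Wsv))[clfs$features]

  base_acc <- mean(stats::predict(clfs$nb, clfs$x) == clfs$y)
  nb_imp <- local_seed(seed, {
    vapply(clfs$features, function(f) {
      drops <- vapply(seq_len(n_permutations), function(i) {
        xp <- clfs$x
        xp[[f]] <- sample(xp[[f]])
        base_acc - mean(stats::predict(clfs$nb, xp) == clfs$y)
      }, 0)
      mean(drops)
    }, 0)
  })

  imp <- data.frame(feature = clfs$features,
                    naive_bayes = unname(nb_imp),
                    svm = unname(sv_imp),
                    random_forest = unname(rf_imp),
                    stringsAsFactors = FALSE)
  top <- lapply(c(naive_bayes = "naive_bayes", svm = "svm",
                  random_forest = "random_forest"), function(cl) {
    imp$feature[order(-imp[[cl]], imp$feature)][seq_len(top_n)]
  })
  all_top <- unlist(top)
  overlap <- unique(all_top[duplicated(all_top)])
  list(importance = imp, top = top, top_n = top_n, overlap = overlap)
}

#' Marker specifications for criterion 2
#'
#' @param node marker node names.
#' @param direction optional expected direction (`"up"`/`"down"`, desired
#'   vs undesired); `NA` means resolve from the phenotype attractors.
#' @param group optional phenotype-set label; the 90% threshold is applied
#'   independently within each group.
#' @return a `marker_spec` data frame.
#' @export
marker_spec <- function(node, direction = NA_character_, group = "all") {
  structure(data.frame(node = node,
                       direction = rep_len(as.character(direction),
                                           length(node)),
                       group = rep_len(as.character(group), length(node)),
                       stringsAsFactors = FALSE),
            class = c("marker_spec", "data.frame"))
}

#' Filtering criterion 2: internal-marker expression ranges
#'
#' For each surviving scheme and replicate, each marker's attractor value
#' is checked against the phenotype attractor ranges. Under `"strict"`
#' mode the value must move past the desired-phenotype range boundary in
#' the expected direction (above `min(desired)` for up markers, below
#' `max(desired)` for down markers); under `"relaxed"` mode it must merely
#' move past the undesired values (above `max(undesired)` / below
#' `min(undesired)`). A scheme passes a replicate iff the fraction of
#' passing markers is at least `threshold` within every marker group
#' independently. Markers whose direction cannot be resolved (identical
#' desired and undesired values, and no literature direction) are excluded
#' from the denominator with a warning. Markers overridden by the scheme
#' itself are evaluated at their override value and flagged.
#'
#' @param screen a `screen_result` (typically restricted to criterion-1
#'   survivors via `which_schemes`).
#' @param markers a [marker_spec()] data frame.
#' @param desired_values,undesired_values numeric matrices nodes x
#'   replicates of the experimental-phenotype attractor values (e.g.
#'   columns of the landscape).
#' @param threshold passing-marker fraction required (default 0.9).
#' @param mode `"strict"` or `"relaxed"`.
#' @param which_schemes integer indices of schemes to evaluate (default
#'   all).
#' @return list with `per_replicate` (logical matrix schemes-evaluated x
#'   replicates), `verdict` (named logical, pass on all replicates),
#'   `fractions` (minimum per-group passing fraction, schemes x
#'   replicates), `detail` (per replicate, marker pass matrices),
#'   `excluded_markers`, `scheme_ids`.
#' @export
criterion2 <- function(screen, markers, desired_values, undesired_values,
                       threshold = 0.9, mode = c("strict", "relaxed"),
                       which_schemes = seq_along(screen$scheme_ids)) {
  mode <- match.arg(mode)
  stopifnot(inherits(screen, "screen_result"), is.data.frame(markers),
            threshold >= 0, threshold <= 1)
  if (is.null(markers$group)) markers$group <- "all"
  if (is.null(markers$direction)) markers$direction <- NA_character_
  nodes <- markers$node
  bad <- setdiff(nodes, rownames(screen$values[[1]]))
  if (length(bad)) stop("marker(s) not in network: ",
                        paste(bad, collapse = ", "))

  des <- desired_values[nodes, , drop = FALSE]
  und <- undesired_values[nodes, , drop = FALSE]
  dir <- markers$direction
  resolved_dir <- ifelse(!is.na(dir), dir,
                         ifelse(rowMeans(des) > rowMeans(und), "up",
                                ifelse(rowMeans(des) < rowMeans(und), "down",
                                       NA_character_)))
  excluded <- nodes[is.na(resolved_dir)]
  if (length(excluded)) {
    warning("marker(s) with unresolvable direction excluded from the ",
            "denominator: ", paste(excluded, collapse = ", "))
  }
  use <- !is.na(resolved_dir)
  if (!any(use)) stop("no usable markers remain")

  # per-marker boundary in the expected direction
  bound <- ifelse(resolved_dir == "up",
                  if (mode == "strict") apply(des, 1, min)
                  else apply(und, 1, max),
                  if (mode == "strict") apply(des, 1, max)
                  else apply(und, 1, min))

  ids <- screen$scheme_ids[which_schemes]
  per_rep <- matrix(NA, length(which_schemes), length(screen$replicates),
                    dimnames = list(ids, screen$replicates))
  fractions <- per_rep
  detail <- vector("list", length(screen$replicates))
  names(detail) <- screen$replicates
  groups <- unique(markers$group[use])
  for (r in seq_along(screen$replicates)) {
    V <- screen$values[[r]][nodes, which_schemes, drop = FALSE]
    pass_m <- matrix(NA, sum(use), length(which_schemes),
                     dimnames = list(nodes[use], ids))
    ui <- which(use)
    for (k in seq_along(ui)) {
      i <- ui[k]
      pass_m[k, ] <- if (resolved_dir[i] == "up") V[i, ] > bound[i]
                     else V[i, ] < bound[i]
    }
    gfrac <- vapply(groups, function(gr) {
      sel <- markers$group[use] == gr
      colMeans(pass_m[sel, , drop = FALSE])
    }, numeric(length(which_schemes)))
    if (is.null(dim(gfrac))) gfrac <- matrix(gfrac, nrow = 1)
    minfrac <- apply(gfrac, 1, min)
    fractions[, r] <- minfrac
    per_rep[, r] <- minfrac >= threshold & screen$converged[[r]][which_schemes]
    detail[[r]] <- pass_m
  }
  verdict <- stats::setNames(rowSums(!per_rep) == 0, ids)
  list(per_replicate = per_rep, verdict = verdict, fractions = fractions,
       detail = detail, excluded_markers = excluded,
       markers_also_control = intersect(nodes, screen$schemes$nodes),
       mode = mode, threshold = threshold, scheme_ids = ids)
}

#' Rank the surviving schemes
#'
#' Survivors (schemes passing criterion 1 on all replicates and criterion
#' 2 on all replicates) are sorted by the number of perturbed nodes
#' ascending, then by scheme id, so the smallest intervention sets come
#' first. Recurring node assignments across survivors are tabulated.
#'
#' @param screen a `screen_result`.
#' @param c1 output of [criterion1()].
#' @param c2 output of [criterion2()].
#' @return a `filter_report`: list with `survivors` (data frame scheme_id,
#'   n_perturbed), `recurrence` (data frame node:symbol assignment,
#'   frequency among survivors), `n_schemes`, `n_pass_c1`, `n_pass_c2`,
#'   `note` (set when no scheme survives).
#' @export
summarize_survivors <- function(screen, c1, c2) {
  ids_c1 <- names(c1$verdict)[c1$verdict]
  ids_c2 <- names(c2$verdict)[c2$verdict]
  surv <- intersect(ids_c1, ids_c2)
  idx <- match(surv, screen$scheme_ids)
  n_pert <- rowSums(screen$schemes$assignment[idx, , drop = FALSE] != 0L)
  ord <- order(n_pert, surv)
  survivors <- data.frame(scheme_id = surv[ord],
                          n_perturbed = unname(n_pert[ord]),
                          stringsAsFactors = FALSE)
  recurrence <- data.frame(assignment = character(0), frequency = numeric(0))
  note <- NULL
  if (nrow(survivors) > 0) {
    asg <- screen$schemes$assignment[idx, , drop = FALSE]
    tab <- unlist(lapply(seq_along(screen$schemes$nodes), function(j) {
      act <- asg[, j] != 0L
      if (!any(act)) return(NULL)
      tapply(act, paste0(screen$schemes$nodes[j], ":",
                         SYMBOLS[asg[, j] + 1L]), sum)
    }))
    tab <- tab[!grepl(":unchanged$", names(tab))]
    recurrence <- data.frame(assignment = names(tab),
                             frequency = unname(tab) / nrow(survivors),
                             stringsAsFactors = FALSE)
    recurrence <- recurrence[order(-recurrence$frequency,
                                   recurrence$assignment), , drop = FALSE]
    rownames(recurrence) <- NULL
  } else {
    note <- paste("no scheme passed both criteria; consider the relaxed",
                  "mode, a lower threshold, or revised markers")
  }
  structure(list(survivors = survivors, recurrence = recurrence,
                 n_schemes = length(screen$scheme_ids),
                 n_pass_c1 = length(ids_c1), n_pass_c2 = length(surv),
                 note = note),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:", x$n_schemes, "schemes ->", x$n_pass_c1,
      "passed criterion 1 ->", x$n_pass_c2, "passed both\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  else if (nrow(x$survivors)) {
    cat("  best (fewest perturbations):", x$survivors$scheme_id[1], "\n")
  }
  invisible(x)
}
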