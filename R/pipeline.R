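#' Pipeline configuration
#'
#' Collects the tunable parameters of [run_pipeline()] with the
#' conventional defaults: FDR threshold 0.05, |log2FC| threshold 0.6,
#' two predictive components, 7-fold cross-validation, 200 permutations,
#' 500 forest trees, square-root block weighting, coverage-based minimal
#' networks, and an explicit seed (no silent nondeterminism).
#'
#' @param alpha FDR significance threshold.
#' @param fc_threshold Absolute log2 fold-change threshold.
#' @param n_components Predictive PLS-DA components.
#' @param n_folds Cross-validation folds for Q2Y.
#' @param n_permutations Label permutations for model validation.
#' @param vip_threshold `"auto"` (normality-plot rule) or a numeric
#'   manual threshold (e.g. 1.5 or 1.4).
#' @param rf_trees Random-forest trees for block selection.
#' @param weighting Block weighting, `"sqrt"` or `"linear"`.
#' @param minimal_criterion `"coverage"` or `"connectivity"`.
#' @param seed Integer seed controlling every stochastic stage.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(alpha = 0.05, fc_threshold = 0.6,
                            n_components = 2L, n_folds = 7L,
                            n_permutations = 200L, vip_threshold = "auto",
                            rf_trees = 500L,
                            weighting = c("sqrt", "linear"),
                            minimal_criterion = c("coverage", "connectivity"),
                            seed = 1L) {
  weighting <- match.arg(weighting)
  minimal_criterion <- match.arg(minimal_criterion)
  stopifnot(alpha > 0, fc_threshold > 0, n_components >= 1, n_folds >= 2,
            n_permutations >= 1, rf_trees >= 1)
  if (is.null(seed) || is.na(seed)) {
    stop("a seed must be set (no silent nondeterminism)", call. = FALSE)
  }
  structure(list(alpha = alpha, fc_threshold = fc_threshold,
                 n_components = as.integer(n_components),
                 n_folds = as.integer(n_folds),
                 n_permutations = as.integer(n_permutations),
                 vip_threshold = vip_threshold,
                 rf_trees = as.integer(rf_trees),
                 weighting = weighting,
                 minimal_criterion = minimal_criterion,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# FNV-1a hash of a string, reported as 8 hex digits; used to fingerprint
# the configuration in the run manifest.
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    # xor on the low 16 bits only (the byte never touches the high half),
    # keeping h a double in [0, 2^32) to stay clear of R's integer range
    lo <- h %% 65536
    h <- (h - lo) + bitwXor(as.integer(lo), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

as_input_matrix <- function(features) {
  if (is.character(features)) read_features(features) else as.matrix(features)
}
as_input_df <- function(x, reader) {
  if (is.character(x)) reader(x) else x
}

validate_pipeline_inputs <- function(features, metadata) {
  problems <- character(0)
  missing_meta <- setdiff(rownames(features), metadata$sample_id)
  if (length(missing_meta)) {
    problems <- c(problems, paste0("samples without metadata: ",
                                   paste(missing_meta, collapse = ", ")))
  }
  missing_feat <- setdiff(metadata$sample_id, rownames(features))
  if (length(missing_feat)) {
    problems <- c(problems, paste0("metadata rows without features: ",
                                   paste(missing_feat, collapse = ", ")))
  }
  groups <- unique(metadata$group)
  if (length(groups) != 2L) {
    problems <- c(problems, paste0("group label must be binary; found: ",
                                   paste(groups, collapse = ", ")))
  }
  if (length(problems)) {
    stop("pipeline input validation failed:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  invisible(TRUE)
}

write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full multiblock differential-analysis pipeline
#'
#' Executes, in order: PQN normalization and autoscaling; the univariate
#' Mann-Whitney/FDR/fold-change screen; PLS-DA with permutation
#' validation and VIP selection; per-block OPLS-DA superscores with the
#' blocked-vs-unblocked sanity check and random-forest block selection;
#' and per-group shrinkage partial-correlation networks with minimal
#' network extraction, Term-from-Prem subtraction, betweenness and hub
#' selection. All stage outputs are written as CSV/JSON under `out_dir`
#' (`preprocess/`, `univariate/`, `latent/`, `multiblock/`, `network/`,
#' `report.json`, `manifest.json`).
#'
#' @param features Path to `features.csv` or a samples x metabolites
#'   matrix of strictly positive raw intensities.
#' @param metadata Path to `metadata.csv` or a data.frame with
#'   `sample_id` and binary `group` (`Term`/`Prem`).
#' @param blocks Path to `blocks.csv` or an annotation data.frame.
#' @param out_dir Output directory (created if absent).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage results plus the `manifest`.
#' @export
run_pipeline <- function(features, metadata, blocks, out_dir,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  features <- as_input_matrix(features)
  metadata <- as_input_df(metadata, read_metadata)
  blocks <- as_input_df(blocks, read_blocks)
  validate_pipeline_inputs(features, metadata)
  metadata <- metadata[match(rownames(features), metadata$sample_id), ]
  groups <- factor(metadata$group, levels = c("Term", "Prem"))
  warnings_log <- character(0)
  note <- function(w) warnings_log <<- c(warnings_log, w)

  for (d in c("", "preprocess", "univariate", "latent", "multiblock",
              "network")) {
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  set.seed(config$seed)

  # -- preprocess ------------------------------------------------------
  pqn <- pqn_normalize(features)
  xs <- withCallingHandlers(
    autoscale(pqn$normalized),
    warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
  write_stage_csv(data.frame(sample_id = names(pqn$dilution_coefficients),
                             dilution_coefficient = pqn$dilution_coefficients),
                  out_dir, "preprocess/dilution_coefficients.csv")

  # -- univariate ------------------------------------------------------
  univ <- univariate_screen(pqn$normalized[, colnames(xs), drop = FALSE],
                            groups, alpha = config$alpha,
                            fc_threshold = config$fc_threshold)
  write_stage_csv(as.data.frame(univ), out_dir, "univariate/univariate.csv")

  # -- latent ----------------------------------------------------------
  fit <- plsda(xs, groups, ncomp = config$n_components)
  perm <- permutation_test(pqn$normalized[, colnames(xs), drop = FALSE],
                           groups, ncomp = config$n_components,
                           n_permutations = config$n_permutations,
                           n_folds = config$n_folds)
  vips <- vip(fit)
  vip_sel <- if (identical(config$vip_threshold, "auto")) {
    normality_threshold(vips)
  } else {
    normality_threshold(vips, threshold = as.numeric(config$vip_threshold))
  }
  write_stage_csv(data.frame(sample_id = rownames(fit$scores), fit$scores,
                             group = as.character(groups)),
                  out_dir, "latent/scores.csv")
  write_stage_csv(data.frame(metabolite = names(vips), vip = as.numeric(vips),
                             selected = vip_sel$selected),
                  out_dir, "latent/vip.csv")
  jsonlite::write_json(
    list(R2Y = fit$R2Y, Q2Y = perm$Q2Y, p_R2Y = perm$p_R2Y, p_Q2 = perm$p_Q2,
         n_components = config$n_components,
         vip_threshold = if (is.finite(vip_sel$threshold)) vip_sel$threshold else "Inf",
         n_vip_selected = vip_sel$n_selected),
    file.path(out_dir, "latent/model_summary.json"),
    auto_unbox = TRUE, digits = NA)

  # -- multiblock ------------------------------------------------------
  bmap <- withCallingHandlers(
    assign_blocks(blocks, colnames(xs)),
    message = function(m) { note(conditionMessage(m)); invokeRestart("muffleMessage") })
  superscores <- withCallingHandlers(
    block_superscores(xs, groups, bmap, weighting = config$weighting),
    warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
  blocked_val <- validate_blocked_model(xs, groups, superscores,
                                        n_permutations = config$n_permutations,
                                        ncomp = config$n_components)
  importance <- random_forest_importance(superscores, groups,
                                         n_trees = config$rf_trees)
  write_stage_csv(data.frame(sample_id = rownames(superscores),
                             unclass(superscores), check.names = FALSE),
                  out_dir, "multiblock/block_scores.csv")
  write_stage_csv(as.data.frame(importance), out_dir,
                  "multiblock/block_importance.csv")
  jsonlite::write_json(
    list(n_blocks = length(bmap),
         discarded_blocks = attr(bmap, "discarded"),
         blocked_unblocked_r = blocked_val$r,
         distorted = blocked_val$distorted,
         blocked = list(R2Y = blocked_val$blocked$R2Y,
                        Q2Y = blocked_val$blocked$Q2Y,
                        p_R2Y = blocked_val$blocked$p_R2Y,
                        p_Q2 = blocked_val$blocked$p_Q2),
         unblocked = list(R2Y = blocked_val$unblocked$R2Y,
                          Q2Y = blocked_val$unblocked$Q2Y,
                          p_R2Y = blocked_val$unblocked$p_R2Y,
                          p_Q2 = blocked_val$unblocked$p_Q2),
         n_rf_selected = sum(importance$selected)),
    file.path(out_dir, "multiblock/blocked_model_summary.json"),
    auto_unbox = TRUE, digits = NA)

  # -- network ---------------------------------------------------------
  nets <- lapply(c(Prem = "Prem", Term = "Term"), function(g) {
    full <- build_network(unclass(superscores)[groups == g, , drop = FALSE])
    list(full = full,
         minimal = minimal_network(full, criterion = config$minimal_criterion))
  })
  diff_net <- differential_network(nets$Prem$minimal, nets$Term$minimal)
  hubs <- select_hub_blocks(diff_net$betweenness,
                            threshold = if (length(diff_net$nodes) < 10L) Inf
                                        else NULL)
  for (g in c("Prem", "Term")) {
    write_stage_csv(nets[[g]]$full$edges, out_dir,
                    sprintf("network/full_edges_%s.csv", tolower(g)))
    write_stage_csv(nets[[g]]$minimal$edges, out_dir,
                    sprintf("network/minimal_edges_%s.csv", tolower(g)))
  }
  write_stage_csv(diff_net$edges, out_dir, "network/differential_edges.csv")
  write_stage_csv(data.frame(block = names(diff_net$betweenness),
                             betweenness = as.numeric(diff_net$betweenness),
                             hub = names(diff_net$betweenness) %in% hubs$hubs),
                  out_dir, "network/betweenness.csv")

  # -- report + manifest -----------------------------------------------
  counts <- attr(univ, "counts")
  report <- list(
    n_samples = nrow(features), n_metabolites = ncol(xs),
    groups = as.list(table(groups)),
    univariate = list(up = unname(counts["up"]), down = unname(counts["down"]),
                      ns = unname(counts["ns"])),
    latent = list(R2Y = fit$R2Y, Q2Y = perm$Q2Y, p_R2Y = perm$p_R2Y,
                  p_Q2 = perm$p_Q2, n_vip_selected = vip_sel$n_selected),
    multiblock = list(n_blocks = length(bmap),
                      n_rf_selected = sum(importance$selected),
                      rf_selected = importance$block[importance$selected],
                      blocked_unblocked_r = blocked_val$r,
                      distorted = blocked_val$distorted),
    network = list(n_minimal_edges_prem = nrow(nets$Prem$minimal$edges),
                   n_minimal_edges_term = nrow(nets$Term$minimal$edges),
                   n_differential_edges = nrow(diff_net$edges),
                   hubs = hubs$hubs)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  manifest <- list(config = unclass(config),
                   config_hash = fnv1a(as.character(cfg_json)),
                   seed = config$seed,
                   stages = c("preprocess", "univariate", "latent",
                              "multiblock", "network"),
                   package_version = as.character(utils::packageVersion("metabloc")),
                   warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(pqn = pqn, autoscaled = xs, univariate = univ, model = fit,
                 permutation = perm, vip = vips, vip_selection = vip_sel,
                 block_map = bmap, block_scores = superscores,
                 blocked_validation = blocked_val, importance = importance,
                 networks = nets, differential = diff_net, hubs = hubs,
                 report = report, manifest = manifest))
}

#' Confounder subgroup PLS-DA models
#'
#' Stratifies the cohort by a metadata covariate and refits the Prem vs
#' Term PLS-DA within each stratum, tabulating R2Y, Q2Y and permutation
#' p-values so the group contrast can be checked for confounding. Strata
#' that do not retain both classes with at least `min_n` samples each
#' are skipped with a warning.
#'
#' @param features Raw feature matrix or path (PQN is applied
#'   internally).
#' @param metadata Metadata data.frame or path; must contain
#'   `stratify_by`.
#' @param stratify_by Name of the covariate column.
#' @param config A [pipeline_config()].
#' @param min_n Minimum per-class samples within a stratum (default 5).
#' @return data.frame with one row per usable stratum: `stratum`,
#'   `n_term`, `n_prem`, `R2Y`, `Q2Y`, `p_R2Y`, `p_Q2`.
#' @export
subgroup_models <- function(features, metadata, stratify_by,
                            config = pipeline_config(), min_n = 5L) {
  features <- as_input_matrix(features)
  metadata <- as_input_df(metadata, read_metadata)
  validate_pipeline_inputs(features, metadata)
  if (!stratify_by %in% names(metadata)) {
    stop("covariate '", stratify_by, "' not present in metadata", call. = FALSE)
  }
  metadata <- metadata[match(rownames(features), metadata$sample_id), ]
  set.seed(config$seed)
  pqn <- pqn_normalize(features)
  rows <- list()
  for (lv in unique(metadata[[stratify_by]])) {
    in_stratum <- metadata[[stratify_by]] == lv
    tab <- table(metadata$group[in_stratum])
    if (length(tab) < 2L || any(tab < min_n)) {
      warning("stratum '", lv, "' skipped: needs both classes with >= ",
              min_n, " samples", call. = FALSE)
      next
    }
    x <- pqn$normalized[in_stratum, , drop = FALSE]
    keep <- apply(x, 2L, stats::sd) > 0
    x <- x[, keep, drop = FALSE]
    g <- factor(metadata$group[in_stratum], levels = c("Term", "Prem"))
    perm <- permutation_test(x, g, ncomp = config$n_components,
                             n_permutations = config$n_permutations,
                             n_folds = config$n_folds)
    rows[[as.character(lv)]] <- data.frame(
      stratum = as.character(lv),
      n_term = unname(tab["Term"]), n_prem = unname(tab["Prem"]),
      R2Y = perm$R2Y, Q2Y = perm$Q2Y, p_R2Y = perm$p_R2Y, p_Q2 = perm$p_Q2,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    stop("no stratum retains both classes with >= ", min_n,
         " samples", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
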