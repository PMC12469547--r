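#' Configuration for the synthetic two-group metabolomics generator
#'
#' Builds and validates the parameter set for [generate_dataset()]. Defaults
#' emulate an NMR-scale urine study: 96 term and 45 preterm neonates, 74
#' features organised into 14 functional blocks, with roughly 46% of
#' metabolites differential between groups and per-sample multiplicative
#' dilution of the kind probabilistic quotient normalization removes.
#'
#' @param n_term,n_prem Number of samples in the Term and Prem groups.
#' @param n_metabolites Number of metabolite features.
#' @param n_blocks Number of functional blocks. Each metabolite gets one
#'   primary block (its latent signal source) plus up to
#'   `max_blocks_per_metabolite - 1` secondary annotations.
#' @param max_blocks_per_metabolite Maximum functional annotations per
#'   metabolite; must lie in 1..3.
#' @param frac_differential Fraction of metabolites carrying a planted
#'   group effect.
#' @param frac_focal_blocks Fraction of blocks designated as focal
#'   (strongly dysregulated). All members of a focal block are planted
#'   with fold changes from the upper half of `log2fc_magnitudes`; the
#'   remaining differential quota is spread over other metabolites with
#'   magnitudes from the lower half. This concentrates dysregulation in
#'   a minority of functional blocks, the structure the block-selection
#'   stages are designed to detect.
#' @param log2fc_magnitudes Length-2 positive range from which planted
#'   |log2 fold changes| are drawn uniformly. Signs are split evenly
#'   between up- and down-regulation in the Prem group.
#' @param dilution_sd Standard deviation (log scale) of the per-sample
#'   multiplicative dilution factor.
#' @param within_block_rho Target correlation (log scale) between
#'   metabolites sharing a primary block, in \[0, 1).
#' @param n_prem_specific_edges Number of block-block dependence edges
#'   present only in the Prem group. Edges are laid out as a star forest
#'   (hubs with ~2 leaves each) over a random block permutation, so the
#'   planted dependence both covers the node set and creates betweenness
#'   hubs. Default `n_blocks - floor(n_blocks / 3)` spans all blocks.
#'   The dependence is carried by per-block, per-sample dysregulation
#'   severity factors that modulate differential members along their
#'   effect directions (see `severity_sd`), the component of block
#'   variation that per-block OPLS-DA t1 scores retain.
#' @param edge_strength Correlation transferred from a star hub's
#'   severity factor to each leaf's, in (0, 1).
#' @param severity_sd Standard deviation (log2 scale) of the per-sample
#'   modulation of planted effects by the block severity factor, applied
#'   to Prem samples only. Encodes inter-individual heterogeneity in how
#'   strongly a function is dysregulated in the preterm group (preterm
#'   cohorts are markedly more heterogeneous than term ones); 0 disables
#'   the severity layer (and with it any expressed block-block
#'   dependence).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal measurement noise.
#' @param differential_blocks Optional character vector of block labels;
#'   when given, planted differential metabolites are drawn only from
#'   metabolites whose primary block is listed.
#' @param seed Integer seed; identical configurations give identical
#'   datasets.
#' @return A validated list of class `"synth_config"`.
#' @seealso [generate_dataset()], [write_fixtures()]
#' @export
synth_config <- function(n_term = 96L, n_prem = 45L,
                         n_metabolites = 74L, n_blocks = 14L,
                         max_blocks_per_metabolite = 3L,
                         frac_differential = 0.46,
                         frac_focal_blocks = 0.15,
                         log2fc_magnitudes = c(0.2, 1.5),
                         dilution_sd = 0.3,
                         within_block_rho = 0.5,
                         n_prem_specific_edges = NULL,
                         edge_strength = 0.85,
                         severity_sd = 0.3,
                         noise_cv = 0.12,
                         differential_blocks = NULL,
                         seed = 1L) {
  if (is.null(n_prem_specific_edges)) {
    n_prem_specific_edges <- n_blocks - floor(n_blocks / 3)
  }
  cfg <- list(
    n_term = as.integer(n_term), n_prem = as.integer(n_prem),
    n_metabolites = as.integer(n_metabolites), n_blocks = as.integer(n_blocks),
    max_blocks_per_metabolite = as.integer(max_blocks_per_metabolite),
    frac_differential = frac_differential,
    frac_focal_blocks = frac_focal_blocks,
    log2fc_magnitudes = as.numeric(log2fc_magnitudes),
    dilution_sd = dilution_sd,
    within_block_rho = within_block_rho,
    n_prem_specific_edges = as.integer(n_prem_specific_edges),
    edge_strength = edge_strength,
    severity_sd = severity_sd,
    noise_cv = noise_cv,
    differential_blocks = differential_blocks,
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stop_field <- function(field, msg) {
    stop(sprintf("invalid synth_config field '%s': %s", field, msg),
         call. = FALSE)
  }
  for (f in c("n_term", "n_prem", "n_metabolites", "n_blocks")) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L) {
      stop_field(f, "must be a single positive count")
    }
  }
  if (cfg$n_term + cfg$n_prem < 10L) {
    stop_field("n_term", "n_term + n_prem must be at least 10")
  }
  if (cfg$max_blocks_per_metabolite < 1L || cfg$max_blocks_per_metabolite > 3L) {
    stop_field("max_blocks_per_metabolite", "must lie in 1..3")
  }
  if (is.na(cfg$frac_differential) || cfg$frac_differential < 0 ||
      cfg$frac_differential > 1) {
    stop_field("frac_differential", "must lie in [0, 1]")
  }
  if (is.na(cfg$frac_focal_blocks) || cfg$frac_focal_blocks < 0 ||
      cfg$frac_focal_blocks > 1) {
    stop_field("frac_focal_blocks", "must lie in [0, 1]")
  }
  if (length(cfg$log2fc_magnitudes) != 2L || any(cfg$log2fc_magnitudes <= 0) ||
      diff(cfg$log2fc_magnitudes) < 0) {
    stop_field("log2fc_magnitudes", "must be an increasing positive range")
  }
  if (cfg$dilution_sd <= 0) stop_field("dilution_sd", "must be positive")
  if (cfg$within_block_rho < 0 || cfg$within_block_rho >= 1) {
    stop_field("within_block_rho", "must lie in [0, 1)")
  }
  if (cfg$n_prem_specific_edges < 0) {
    stop_field("n_prem_specific_edges", "must be non-negative")
  }
  if (cfg$edge_strength <= 0 || cfg$edge_strength >= 1) {
    stop_field("edge_strength", "must lie in (0, 1)")
  }
  if (is.na(cfg$severity_sd) || cfg$severity_sd < 0) {
    stop_field("severity_sd", "must be non-negative")
  }
  if (cfg$noise_cv <= 0) stop_field("noise_cv", "must be positive")
  if (length(cfg$seed) != 1L || is.na(cfg$seed)) {
    stop_field("seed", "must be a single integer")
  }
  invisible(cfg)
}

# Star-forest layout of prem-specific block dependence: consume a random
# permutation of blocks four at a time (hub + three leaves); any final
# remainder (<4 blocks) is attached as extra leaves of the last hub.
star_forest_edges <- function(block_labels, n_edges) {
  n <- length(block_labels)
  if (n_edges == 0L || n < 2L) {
    return(list(edges = character(0), hubs = character(0),
                edge_table = data.frame(node_a = character(0),
                                        node_b = character(0))))
  }
  perm <- sample(block_labels)
  # partition into stars of 3 blocks (hub + 2 leaves): small stars keep the
  # hub-leaf partial correlations strong (they dilute with leaf count) while
  # still creating betweenness hubs; the division remainder is spread one
  # block at a time over the last stars so star sizes stay balanced
  n_stars <- max(1L, n %/% 3L)
  sizes <- rep(3L, n_stars)
  rem <- n - sum(sizes)
  if (rem > 0L && n_stars >= 1L) {
    grow <- (n_stars - rem + 1L):n_stars
    sizes[grow] <- sizes[grow] + 1L
  }
  if (n < 3L) sizes <- n
  a <- character(0); b <- character(0); hubs <- character(0)
  i <- 1L
  for (sz in sizes) {
    if (length(a) >= n_edges) break
    hub <- perm[i]
    k <- sz - 1L
    if (k < 1L) break
    hubs <- c(hubs, hub)
    leaves <- perm[(i + 1L):(i + k)]
    a <- c(a, rep(hub, k)); b <- c(b, leaves)
    i <- i + sz
  }
  keep <- seq_len(min(length(a), n_edges))
  a <- a[keep]; b <- b[keep]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  list(edges = paste(a, b, sep = "--"),
       hubs = intersect(hubs, c(a, b)),
       edge_table = data.frame(node_a = a, node_b = b,
                               stringsAsFactors = FALSE))
}

#' Generate a synthetic two-group block-structured metabolomics dataset
#'
#' Simulates a samples-by-metabolites positive intensity matrix under a
#' multiplicative generative model: per-sample block latent factors,
#' per-block dysregulation severity factors (with group-specific
#' block-block dependence in the Prem group), log-normal metabolite
#' baselines, planted group fold changes, per-sample dilution, and
#' log-normal measurement noise. On the log scale, for sample i and
#' metabolite j with primary block b,
#' \deqn{\log x_{ij} = \log \beta_j + \lambda z_{b(j),i}
#'   + \ln(2)\,1(i \in Prem)\,[\gamma_j + \tau\, sgn(\gamma_j)\, v_{b(j),i}]
#'   + \log d_i + \epsilon_{ij},}
#' where \eqn{\lambda} is set so two metabolites sharing a primary block
#' correlate at `within_block_rho`, \eqn{\gamma_j} is the planted log2
#' fold change, \eqn{\tau} = `severity_sd`, \eqn{v} the per-block
#' dysregulation severity factors (star-correlated across blocks), and
#' \eqn{d_i} the dilution factor, with
#' \eqn{\epsilon \sim N(0, \log(1 + cv^2))}.
#'
#' @param config A [synth_config()] object.
#' @return A list of class `"synth_dataset"` with elements
#'   \describe{
#'     \item{features}{numeric matrix (samples x metabolites), strictly
#'       positive, attribute `state = "raw"`.}
#'     \item{metadata}{data.frame with `sample_id`, `group`
#'       (`Term`/`Prem`) and two neutral covariates (`sex`, `delivery`).}
#'     \item{blocks}{data.frame `metabolite_id`, `function1..3` (blanks
#'       allowed beyond the first).}
#'     \item{truth}{ground truth: `differential_flags`, `planted_log2fc`,
#'       `block_membership`, `prem_specific_block_edges` (and as a
#'       two-column table), `hub_blocks`, `dilution_factors`.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' d <- generate_dataset(synth_config(n_term = 20, n_prem = 10,
#'                                    n_metabolites = 30, n_blocks = 5,
#'                                    seed = 7))
#' dim(d$features)
#' @export
generate_dataset <- function(config) {
  validate_synth_config(config)
  set.seed(config$seed)
  n <- config$n_term + config$n_prem
  m <- config$n_metabolites
  B <- config$n_blocks

  sample_id <- sprintf("S%03d", seq_len(n))
  group <- factor(c(rep("Term", config$n_term), rep("Prem", config$n_prem)),
                  levels = c("Term", "Prem"))
  met_id <- sprintf("M%03d", seq_len(m))
  block_labels <- sprintf("B%02d", seq_len(B))

  # Block membership: shuffled round-robin primary block guarantees near
  # balanced block sizes; 0-2 random secondary annotations per metabolite.
  primary <- block_labels[rep_len(seq_len(B), m)][sample.int(m)]
  membership <- vector("list", m)
  names(membership) <- met_id
  for (j in seq_len(m)) {
    extra_max <- config$max_blocks_per_metabolite - 1L
    n_extra <- if (extra_max > 0L) {
      sample(0:extra_max, 1L, prob = c(0.85, 0.12, 0.03)[seq_len(extra_max + 1L)])
    } else 0L
    sec <- if (n_extra > 0L) {
      sample(setdiff(block_labels, primary[j]), n_extra)
    } else character(0)
    membership[[j]] <- c(primary[j], sec)
  }

  # Planted differential metabolites, signs split ~50/50. Dysregulation is
  # concentrated: members of a few focal blocks get the large effects, the
  # rest of the differential quota is spread thinly with small effects.
  n_diff <- round(config$frac_differential * m)
  lo <- config$log2fc_magnitudes[1]; hi <- config$log2fc_magnitudes[2]
  mid <- (lo + hi) / 2
  planted_log2fc <- numeric(m)
  focal_blocks <- character(0)
  if (!is.null(config$differential_blocks)) {
    candidates <- which(primary %in% config$differential_blocks)
    n_diff <- min(n_diff, length(candidates))
    flagged <- sort(sample(candidates, n_diff))
    if (n_diff > 0L) {
      planted_log2fc[flagged] <- stats::runif(n_diff, lo, hi)
    }
  } else {
    n_focal <- min(max(round(config$frac_focal_blocks * B), 0L), B)
    focal_blocks <- if (n_focal > 0L) sample(block_labels, n_focal) else character(0)
    # Focal blocks are strongly dysregulated but capped at 4 flagged
    # members each, so the rest of the quota spreads every other block
    # with at least a couple of differential metabolites.
    focal_members <- unlist(lapply(focal_blocks, function(b) {
      mem <- which(primary == b)
      mem[seq_len(min(4L, length(mem)))]
    }))
    focal_members <- focal_members[seq_len(min(length(focal_members), n_diff))]
    # Spread the remaining quota as evenly as possible over the non-focal
    # blocks (round-robin over shuffled members), so every block carries
    # at least a couple of mildly differential metabolites and can express
    # its planted block-block dependence.
    n_rest <- n_diff - length(focal_members)
    others <- integer(0)
    if (n_rest > 0L) {
      pool <- lapply(sample(setdiff(block_labels, focal_blocks)), function(b) {
        sample(which(primary == b))
      })
      pool <- pool[lengths(pool) > 0L]
      round_robin <- integer(0)
      depth <- 1L
      while (length(round_robin) < n_rest && length(pool) > 0L) {
        layer <- unlist(lapply(pool, function(v) {
          if (length(v) >= depth) v[depth] else integer(0)
        }))
        if (length(layer) == 0L) break
        round_robin <- c(round_robin, layer)
        depth <- depth + 1L
      }
      others <- round_robin[seq_len(min(n_rest, length(round_robin)))]
    }
    flagged <- sort(c(focal_members, others))
    planted_log2fc[focal_members] <- stats::runif(length(focal_members), mid, hi)
    planted_log2fc[others] <- stats::runif(length(others), lo, mid)
  }
  # Signs alternate within each block (random phase): a dysregulated
  # function shows both accumulating and depleting members, and the
  # balance keeps the overall up/down split near 50/50. Within-block
  # alternation also cancels the block identity factor out of the
  # class-predictive combination, leaving the severity factor visible.
  if (length(flagged) > 0L) {
    # phases chosen greedily so the global up/down balance stays tight
    # (a skewed balance would bias the PQN median quotient)
    imbalance <- 0L
    for (b in sample(unique(primary[flagged]))) {
      fb <- sample(flagged[primary[flagged] == b])
      signs <- rep_len(c(1L, -1L), length(fb))
      flip <- if (sum(signs) == 0L) stats::runif(1) < 0.5 else
        sign(imbalance) == sign(sum(signs))
      if (flip) signs <- -signs
      imbalance <- imbalance + sum(signs)
      planted_log2fc[fb] <- planted_log2fc[fb] * signs
    }
  }
  differential_flags <- planted_log2fc != 0

  # Prem-specific block dependence: star forest over blocks, carried by
  # per-block dysregulation severity factors. Each block has a per-sample
  # severity v_b (iid across blocks in Term; in Prem, star leaves inherit
  # edge_strength of their hub's severity) that modulates differential
  # members along the sign of their planted effect. Severity variation
  # lies along each block's class-predictive direction, the component of
  # block variation that per-block OPLS-DA t1 scores retain.
  sf <- star_forest_edges(block_labels, config$n_prem_specific_edges)
  v <- matrix(stats::rnorm(n * B), n, B, dimnames = list(sample_id, block_labels))
  if (nrow(sf$edge_table) > 0L) {
    prem_rows <- which(group == "Prem")
    es <- config$edge_strength
    for (r in seq_len(nrow(sf$edge_table))) {
      hub <- sf$edge_table$node_a[r]; leaf <- sf$edge_table$node_b[r]
      if (!(hub %in% sf$hubs)) { tmp <- hub; hub <- leaf; leaf <- tmp }
      v[prem_rows, leaf] <- es * v[prem_rows, hub] +
        sqrt(1 - es^2) * v[prem_rows, leaf]
    }
  }

  # Block identity factors give the within-block correlation (iid across
  # blocks and groups; this class-unrelated shared variation is what the
  # orthogonal component of per-block OPLS-DA removes).
  z <- matrix(stats::rnorm(n * B), n, B, dimnames = list(sample_id, block_labels))

  sigma_e <- sqrt(log(1 + config$noise_cv^2))
  lambda <- sigma_e * sqrt(config$within_block_rho / (1 - config$within_block_rho))
  baseline <- exp(stats::rnorm(m, mean = log(1e4), sd = 1))
  dilution <- exp(stats::rnorm(n, 0, config$dilution_sd))

  logx <- matrix(stats::rnorm(n * m, 0, sigma_e), n, m)
  prem_ind <- as.numeric(group == "Prem")
  effect_sign <- sign(planted_log2fc)
  for (j in seq_len(m)) {
    logx[, j] <- log(baseline[j]) + lambda * z[, primary[j]] +
      log(2) * prem_ind * (planted_log2fc[j] +
                             config$severity_sd * effect_sign[j] *
                               v[, primary[j]]) +
      log(dilution) + logx[, j]
  }
  features <- exp(logx)
  dimnames(features) <- list(sample_id, met_id)
  attr(features, "state") <- "raw"

  metadata <- data.frame(
    sample_id = sample_id,
    group = as.character(group),
    sex = sample(c("M", "F"), n, replace = TRUE),
    delivery = sample(c("vaginal", "cesarean"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )

  blocks <- data.frame(
    metabolite_id = met_id,
    function1 = vapply(membership, function(v) v[1], ""),
    function2 = vapply(membership, function(v) if (length(v) > 1) v[2] else "", ""),
    function3 = vapply(membership, function(v) if (length(v) > 2) v[3] else "", ""),
    stringsAsFactors = FALSE
  )

  truth <- list(
    differential_flags = stats::setNames(differential_flags, met_id),
    planted_log2fc = stats::setNames(planted_log2fc, met_id),
    block_membership = membership,
    prem_specific_block_edges = sf$edges,
    prem_specific_edge_table = sf$edge_table,
    hub_blocks = sf$hubs,
    focal_blocks = focal_blocks,
    severity_factors = v,
    dilution_factors = stats::setNames(dilution, sample_id)
  )

  out <- list(features = features, metadata = metadata, blocks = blocks,
              truth = truth, config = config)
  class(out) <- "synth_dataset"
  out
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat("Synthetic metabolomics dataset\n")
  cat(sprintf("  %d samples (%d Term, %d Prem) x %d metabolites, %d blocks\n",
              nrow(x$features), x$config$n_term, x$config$n_prem,
              ncol(x$features), x$config$n_blocks))
  cat(sprintf("  %d differential metabolites planted; %d Prem-specific block edges\n",
              sum(x$truth$differential_flags),
              length(x$truth$prem_specific_block_edges)))
  invisible(x)
}

#' Write a synthetic dataset to plain-text fixtures
#'
#' Emits `features.csv` (first column `sample_id`, one column per
#' metabolite), `metadata.csv`, `blocks.csv` and, unless `truth = FALSE`,
#' `truth.json`. The CSV files round-trip losslessly through
#' [read_features()], [read_metadata()] and [read_blocks()].
#'
#' @param dataset A `"synth_dataset"` from [generate_dataset()].
#' @param directory Output directory (created if absent).
#' @param truth Write `truth.json` with the planted ground truth?
#' @return Invisibly, the paths written.
#' @export
write_fixtures <- function(dataset, directory, truth = TRUE) {
  stopifnot(inherits(dataset, "synth_dataset"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory, call. = FALSE)
  }
  paths <- c(features = file.path(directory, "features.csv"),
             metadata = file.path(directory, "metadata.csv"),
             blocks = file.path(directory, "blocks.csv"))
  feat <- data.frame(sample_id = rownames(dataset$features),
                     dataset$features, check.names = FALSE,
                     stringsAsFactors = FALSE)
  utils::write.csv(feat, paths["features"], row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$metadata, paths["metadata"], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(dataset$blocks, paths["blocks"], row.names = FALSE,
                   quote = FALSE)
  if (isTRUE(truth)) {
    paths <- c(paths, truth = file.path(directory, "truth.json"))
    tr <- dataset$truth
    tr$block_membership <- lapply(tr$block_membership, as.character)
    tr$severity_factors <- NULL  # full matrix; kept in-memory only
    jsonlite::write_json(tr, paths["truth"], auto_unbox = FALSE, digits = NA,
                         pretty = TRUE)
  }
  invisible(paths)
}

#' Read a features matrix written by [write_fixtures()]
#'
#' @param path Path to `features.csv` (first column `sample_id`).
#' @return Numeric matrix, samples x metabolites, `state = "raw"`.
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id") {
    stop("features file must have 'sample_id' as its first column",
         call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  storage.mode(m) <- "double"
  attr(m, "state") <- "raw"
  m
}

#' Read a sample metadata table
#'
#' @param path Path to `metadata.csv` (`sample_id`, `group`, optional
#'   covariates).
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  if (!all(need %in% names(df))) {
    stop("metadata file must contain columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a metabolite-to-function block annotation table
#'
#' Wide format: `metabolite_id` followed by up to three function columns;
#' blank entries mean no further annotation. More than three function
#' columns is a validation error (a metabolite carries at most three
#' biological functions).
#'
#' @param path Path to `blocks.csv`.
#' @return data.frame with columns `metabolite_id`, `function1..3`.
#' @export
read_blocks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (names(df)[1] != "metabolite_id") {
    stop("blocks file must have 'metabolite_id' as its first column",
         call. = FALSE)
  }
  if (ncol(df) - 1L > 3L) {
    stop("a metabolite may carry at most three function annotations; ",
         "found ", ncol(df) - 1L, " function columns", call. = FALSE)
  }
  for (k in seq_len(3L)) {
    nm <- paste0("function", k)
    if (!nm %in% names(df)) df[[nm]] <- ""
    df[[nm]][is.na(df[[nm]])] <- ""
  }
  df[, c("metabolite_id", "function1", "function2", "function3")]
}
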