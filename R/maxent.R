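# Presence-background maximum-entropy niche model: fitting, prediction,
# AUC evaluation, replicated validation, variable importance and response
# curves.

#' Fit an L1-regularized maximum-entropy model
#'
#' Maximizes the penalized training gain
#' `G(lambda) = mean_presence(eta) - log(mean_background(exp(eta))) -
#' sum_j beta_j * |lambda_j|` with `beta_j = beta_multiplier * s_j / sqrt(m)`
#' (`s_j` = feature sample SD over presence points, `m` = presence count).
#' The objective is concave; it is solved by cyclic coordinate ascent with a
#' per-coordinate Newton step, L1 soft-threshold and step-halving, so the
#' penalized gain is non-decreasing along the recorded trace.
#'
#' @param features A [build_features()] object.
#' @param beta_multiplier Regularization multiplier (>= 0; default 1).
#' @param max_iter Maximum coordinate-ascent cycles.
#' @param tolerance Convergence: stop when a full cycle improves the gain by
#'   less than this.
#' @param presence_rows Optional integer rows of `features$X` to treat as
#'   the presence sample (defaults to `which(features$presence)`); background
#'   rows are always `which(!features$presence)`.  Used by the permutation
#'   tests to refit on pseudo-groups without rebuilding features.
#' @return A `maxent_model`: coefficients, regularization weights, feature
#'   definitions, `log Z` over the background, the entropy of the fitted
#'   background distribution, the training-gain trace and a convergence flag.
#' @export
fit_maxent <- function(features, beta_multiplier = 1, max_iter = 500,
                       tolerance = 1e-7, presence_rows = NULL) {
  stopifnot(inherits(features, "maxent_features"))
  if (beta_multiplier < 0) stop("`beta_multiplier` must be >= 0", call. = FALSE)
  if (is.null(presence_rows)) presence_rows <- which(features$presence)
  background_rows <- which(!features$presence)
  m <- length(presence_rows)
  if (m < 1 || length(background_rows) < 2)
    stop("need >= 1 presence and >= 2 background rows", call. = FALSE)
  X <- features$X
  s_j <- apply(X[presence_rows, , drop = FALSE], 2, stats::sd)
  if (m == 1) s_j[] <- 0
  beta_j <- beta_multiplier * pmax(s_j, 1e-6) / sqrt(m)
  fit <- cpp_maxent_fit(X, as.integer(presence_rows),
                        as.integer(background_rows), beta_j,
                        as.integer(max_iter), tolerance)
  defs <- features$defs
  trace <- data.frame(feature = defs$feature[fit$trace_feature],
                      variable = defs$variable[fit$trace_feature],
                      gain = fit$trace_gain, delta_gain = fit$trace_delta,
                      stringsAsFactors = FALSE)
  pres_env <- features$env[presence_rows, , drop = FALSE]
  cont <- names(pres_env)[features$kind[names(pres_env)] == "continuous"]
  cat_ <- names(pres_env)[features$kind[names(pres_env)] == "categorical"]
  presence_stats <- list(
    mean = vapply(cont, function(v) mean(pres_env[[v]]), numeric(1)),
    mode = vapply(cat_, function(v) {
      tab <- table(pres_env[[v]])
      as.integer(names(tab)[which.max(tab)])
    }, integer(1)))
  structure(list(lambda = stats::setNames(fit$lambda, defs$feature),
                 beta_j = stats::setNames(beta_j, defs$feature),
                 defs = defs, kind = features$kind,
                 gain = fit$gain, logZ = fit$logZ, entropy = fit$entropy,
                 converged = fit$converged, n_cycles = fit$n_cycles,
                 trace = trace,
                 n_presence = m, n_background = length(background_rows),
                 presence_stats = presence_stats,
                 beta_multiplier = beta_multiplier),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> %d feature(s), gain %.4f, %s after %d cycle(s)\n",
              length(x$lambda), x$gain,
              if (x$converged) "converged" else "NOT converged", x$n_cycles))
  nz <- x$lambda[x$lambda != 0]
  if (length(nz)) print(round(nz, 4)) else cat("(all coefficients zero)\n")
  invisible(x)
}

# Linear predictor for arbitrary environmental rows.
model_eta <- function(model, env) {
  drop(apply_features(model$defs, env) %*% model$lambda)
}

#' Predict suitability scores at points
#'
#' @param model A [fit_maxent()] model.
#' @param env Data.frame of source-variable values.
#' @param output `"raw"` (`exp(eta)/Z`, summing to 1 over the training
#'   background), `"cloglog"` (`1 - exp(-exp(H) * raw)` with `H` the entropy
#'   of the fitted background distribution) or `"link"` (the linear
#'   predictor).
#' @return Numeric vector of scores.
#' @export
predict_scores <- function(model, env, output = c("raw", "cloglog", "link")) {
  output <- match.arg(output)
  eta <- model_eta(model, env)
  if (output == "link") return(eta)
  raw <- exp(eta - model$logZ)
  if (output == "raw") raw else 1 - exp(-exp(model$entropy) * raw)
}

#' Predict a suitability surface over a raster stack
#'
#' @param model A [fit_maxent()] model.
#' @param stack A [raster_stack()] supplying every source variable (missing
#'   layers are an error naming the layer).
#' @param output `"raw"` or `"cloglog"` (see [predict_scores()]).  Raw
#'   output sums to 1 when the prediction extent equals the training
#'   background; overlap statistics renormalize over the map regardless.
#' @return A [suitability_grid()] (masked cells propagate).
#' @export
predict_suitability <- function(model, stack, output = c("raw", "cloglog")) {
  output <- match.arg(output)
  stopifnot(inherits(stack, "raster_stack"))
  need <- unique(c(model$defs$variable,
                   model$defs$variable2[!is.na(model$defs$variable2)]))
  missing_layers <- setdiff(need, names(stack$layers))
  if (length(missing_layers))
    stop("stack lacks layer(s): ", paste(missing_layers, collapse = ", "),
         call. = FALSE)
  env <- stack_env_frame(stack)
  vals <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
  vals[attr(env, "cell_index")] <- predict_scores(model, env, output)
  vals[stack$mask] <- 0
  suitability_grid(stack$grid, vals, mask = stack$mask)
}

#' AUC of presence versus background scores
#'
#' The Mann–Whitney statistic with mid-rank tie handling:
#' `AUC = (#(p > b) + 0.5 * #(p = b)) / (n_p * n_b)`.
#'
#' @param scores_presence,scores_background Numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' evaluate_auc(c(0.9, 0.8), c(0.2, 0.1))  # 1
evaluate_auc <- function(scores_presence, scores_background) {
  np <- length(scores_presence); nb <- length(scores_background)
  if (!np || !nb) stop("both score sets must be non-empty", call. = FALSE)
  r <- rank(c(scores_presence, scores_background))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Replicated 80/20 presence-split validation
#'
#' Runs `n_replicates` independent random presence splits (the background is
#' never split), fits on the training fraction and scores the AUC of the
#' held-out presences against the full background.
#'
#' @param features A [build_features()] object.
#' @param n_replicates Number of replicates (default 10).
#' @param test_fraction Held-out presence fraction (default 0.2).
#' @param beta_multiplier,max_iter,tolerance Passed to [fit_maxent()].
#' @param seed Integer seed.
#' @return An `eval_result`: per-replicate AUCs, mean, SD, replicate seeds,
#'   and the per-replicate fitted models (for response-curve bands).
#' @export
crossvalidate <- function(features, n_replicates = 10, test_fraction = 0.2,
                          beta_multiplier = 1, max_iter = 500,
                          tolerance = 1e-7, seed) {
  stopifnot(inherits(features, "maxent_features"))
  pres <- which(features$presence)
  n_test <- floor(length(pres) * test_fraction)
  if (n_test < 1)
    stop("presence count x test_fraction must be >= 1", call. = FALSE)
  with_rng_seed(seed, {
    rep_seeds <- sample.int(.Machine$integer.max, n_replicates)
    aucs <- numeric(n_replicates)
    models <- vector("list", n_replicates)
    bg_scores_env <- features$env[!features$presence, , drop = FALSE]
    for (r in seq_len(n_replicates)) {
      test <- with_rng_seed(rep_seeds[r], sample(pres, n_test))
      train <- setdiff(pres, test)
      fit <- fit_maxent(features, beta_multiplier, max_iter, tolerance,
                        presence_rows = train)
      eta_all <- drop(features$X %*% fit$lambda)
      aucs[r] <- evaluate_auc(eta_all[test], eta_all[!features$presence])
      models[[r]] <- fit
    }
    structure(list(auc = aucs, mean = mean(aucs), sd = stats::sd(aucs),
                   seeds = rep_seeds, models = models,
                   n_replicates = n_replicates, test_fraction = test_fraction),
              class = "eval_result")
  })
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %d replicate(s): mean AUC %.3f (SD %.3f)\n",
              x$n_replicates, x$mean, x$sd))
  invisible(x)
}

#' Percent contribution of each variable
#'
#' Sums the positive penalized-gain increments of every training-trace
#' update, attributed to the updated feature's source variable, and
#' normalizes to 100%.  The accounting is path-dependent (it depends on the
#' coordinate update order), which matches how the measure is convention-
#' ally defined for maxent-style models.
#'
#' @param model A [fit_maxent()] model.
#' @return Named numeric vector summing to 100 (or all zeros, with a
#'   warning, for an all-zero model).
#' @export
percent_contribution <- function(model) {
  vars <- unique(model$defs$variable)
  out <- stats::setNames(rep(0, length(vars)), vars)
  tr <- model$trace
  tr <- tr[tr$delta_gain > 0, , drop = FALSE]
  if (!nrow(tr)) {
    warning("empty training trace; all contributions are zero")
    return(out)
  }
  agg <- tapply(tr$delta_gain, tr$variable, sum)
  out[names(agg)] <- agg
  100 * out / sum(out)
}

#' Permutation importance of each variable
#'
#' For each source variable: permute its raw values across the combined
#' presence + background rows, rebuild that variable's features with the
#' model's stored scalings, rescore, and take
#' `max(0, AUC_original - AUC_permuted)`; normalized to 100% when any
#' importance is positive.
#'
#' @param model A [fit_maxent()] model.
#' @param features The [build_features()] object the model was fit on.
#' @param seed Integer seed for the permutations.
#' @return Named numeric vector (percent).
#' @export
permutation_importance <- function(model, features, seed) {
  stopifnot(inherits(features, "maxent_features"))
  pres <- features$presence
  eta0 <- drop(features$X %*% model$lambda)
  auc0 <- evaluate_auc(eta0[pres], eta0[!pres])
  vars <- unique(model$defs$variable)
  with_rng_seed(seed, {
    drops <- vapply(vars, function(v) {
      jj <- which(model$defs$variable == v |
                  (!is.na(model$defs$variable2) & model$defs$variable2 == v))
      if (all(model$lambda[jj] == 0)) return(0)
      env_perm <- features$env
      env_perm[[v]] <- sample(env_perm[[v]])
      Xv <- apply_features(model$defs[jj, , drop = FALSE], env_perm)
      eta <- eta0 - drop(features$X[, jj, drop = FALSE] %*% model$lambda[jj]) +
        drop(Xv %*% model$lambda[jj])
      max(0, auc0 - evaluate_auc(eta[pres], eta[!pres]))
    }, numeric(1))
    if (sum(drops) > 0) 100 * drops / sum(drops) else drops
  })
}

#' Response curve of the model along one variable
#'
#' Varies the target variable over `n_grid` points of its observed
#' (training) range — or its class set, for a categorical variable — holding
#' the other continuous variables at their presence means and categorical
#' variables at their presence modes, and predicts cloglog suitability.
#' When replicate models are supplied (e.g. from [crossvalidate()]), the
#' band is the mean with a 95% t-interval across replicates.
#'
#' @param model A [fit_maxent()] model.
#' @param variable Variable name (must appear in the model).
#' @param n_grid Number of evaluation points for continuous variables.
#' @param replicates Optional list of replicate `maxent_model`s.
#' @return A data.frame: `value`, `suitability`, and `lower`/`upper` when
#'   replicates are given.
#' @export
response_curve <- function(model, variable, n_grid = 100, replicates = NULL) {
  defs <- model$defs
  if (!variable %in% c(defs$variable, defs$variable2))
    stop(sprintf("variable '%s' is not in the model", variable), call. = FALSE)
  is_cat <- identical(unname(model$kind[variable]), "categorical")
  if (is_cat) {
    values <- sort(defs$level[defs$variable == variable])
  } else {
    d <- defs[defs$variable == variable & !is.na(defs$a), ][1, ]
    values <- seq(d$a, d$b, length.out = n_grid)
  }
  base <- data.frame(row.names = seq_along(values))
  for (v in names(model$presence_stats$mean))
    base[[v]] <- model$presence_stats$mean[[v]]
  for (v in names(model$presence_stats$mode))
    base[[v]] <- model$presence_stats$mode[[v]]
  base[[variable]] <- values
  preds <- predict_scores(model, base, output = "cloglog")
  out <- data.frame(value = values, suitability = preds)
  if (!is.null(replicates) && length(replicates) > 1) {
    mat <- vapply(replicates, function(m)
      predict_scores(m, base, output = "cloglog"), numeric(length(values)))
    mu <- rowMeans(mat)
    half <- stats::qt(0.975, df = ncol(mat) - 1) *
      apply(mat, 1, stats::sd) / sqrt(ncol(mat))
    out$suitability <- mu
    out$lower <- mu - half
    out$upper <- mu + half
  }
  out
}
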