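# Feature expansion for the maximum-entropy model: linear, quadratic,
# product and hinge transforms of continuous variables (min-max scaled to
# [0, 1] over presence + background) and one-hot indicators for categorical
# variables.

# Build the feature definition table from training data.
.feature_defs <- function(env_all, kinds, classes, n_hinge_knots,
                          presence_rows) {
  defs <- list()
  add <- function(...) defs[[length(defs) + 1L]] <<- data.frame(...,
    stringsAsFactors = FALSE)
  cont <- names(env_all)[kinds[names(env_all)] == "continuous"]
  cat_ <- names(env_all)[kinds[names(env_all)] == "categorical"]
  for (v in cont) {
    a <- min(env_all[[v]]); b <- max(env_all[[v]])
    if (b <= a) b <- a + 1  # constant column: features become 0
    if ("linear" %in% classes)
      add(feature = paste0(v, "_lin"), variable = v, variable2 = NA,
          class = "linear", a = a, b = b, knot = NA_real_, level = NA_integer_)
    if ("quadratic" %in% classes)
      add(feature = paste0(v, "_quad"), variable = v, variable2 = NA,
          class = "quadratic", a = a, b = b, knot = NA_real_,
          level = NA_integer_)
    if ("hinge" %in% classes && n_hinge_knots > 0) {
      pv <- env_all[[v]][presence_rows]
      knots <- unique(stats::quantile(pv, probs =
        seq_len(n_hinge_knots) / (n_hinge_knots + 1), names = FALSE))
      for (kn in knots) {
        if (kn > a && kn < b) {
          add(feature = sprintf("%s_hf_%.6g", v, kn), variable = v,
              variable2 = NA, class = "hinge_fwd", a = a, b = b, knot = kn,
              level = NA_integer_)
          add(feature = sprintf("%s_hr_%.6g", v, kn), variable = v,
              variable2 = NA, class = "hinge_rev", a = a, b = b, knot = kn,
              level = NA_integer_)
        }
      }
    }
  }
  if ("product" %in% classes && length(cont) >= 2) {
    pairs <- utils::combn(cont, 2)
    for (j in seq_len(ncol(pairs))) {
      v1 <- pairs[1, j]; v2 <- pairs[2, j]
      a1 <- min(env_all[[v1]]); b1 <- max(env_all[[v1]])
      a2 <- min(env_all[[v2]]); b2 <- max(env_all[[v2]])
      add(feature = paste0(v1, "_x_", v2), variable = v1, variable2 = v2,
          class = "product", a = a1, b = max(b1, a1 + 1), knot = a2,
          level = NA_integer_)
      # for products, (a, b) scale variable1 and (knot, level slot unused)
      defs[[length(defs)]]$b2 <- max(b2, a2 + 1)
    }
  }
  for (v in cat_) {
    lv <- sort(unique(as.integer(env_all[[v]])))
    if (length(lv) < 2) {
      warning(sprintf("categorical variable '%s' has a single class; indicator dropped", v))
      next
    }
    for (l in lv)
      add(feature = sprintf("%s_is_%d", v, l), variable = v, variable2 = NA,
          class = "categorical", a = NA_real_, b = NA_real_, knot = NA_real_,
          level = l)
  }
  if (!length(defs)) stop("no features could be constructed", call. = FALSE)
  defs <- do.call(rbind, lapply(defs, function(d) {
    if (is.null(d$b2)) d$b2 <- NA_real_
    d
  }))
  rownames(defs) <- NULL
  defs
}

scale01 <- function(v, a, b) pmin(1, pmax(0, (v - a) / (b - a)))

#' Evaluate feature definitions on new data
#'
#' @param defs Feature definition table (from a `maxent_features` object or
#'   a fitted model).
#' @param env Data.frame with the source variable columns.
#' @return Numeric matrix, one column per feature, values in \[0, 1\]
#'   (new data is clamped to the training range).
#' @export
apply_features <- function(defs, env) {
  n <- nrow(env)
  X <- matrix(0, n, nrow(defs), dimnames = list(NULL, defs$feature))
  for (j in seq_len(nrow(defs))) {
    d <- defs[j, ]
    X[, j] <- switch(d$class,
      linear = scale01(env[[d$variable]], d$a, d$b),
      quadratic = scale01(env[[d$variable]], d$a, d$b)^2,
      product = scale01(env[[d$variable]], d$a, d$b) *
                scale01(env[[d$variable2]], d$knot, d$b2),
      hinge_fwd = pmax(0, (pmin(env[[d$variable]], d$b) - d$knot)) /
                  (d$b - d$knot),
      hinge_rev = pmax(0, (d$knot - pmax(env[[d$variable]], d$a))) /
                  (d$knot - d$a),
      categorical = as.numeric(as.integer(env[[d$variable]]) == d$level),
      stop("unknown feature class ", d$class))
  }
  X
}

#' Build the presence/background feature matrix
#'
#' Continuous variables are expanded into the requested feature classes
#' after min-max scaling to \[0, 1\] using the combined presence + background
#' extremes; categorical variables are always expanded to one-hot
#' indicators; hinge features place `n_hinge_knots` forward/reverse hinges at
#' presence-value quantiles.
#'
#' @param env_presence,env_background Environmental matrices from
#'   [extract_env()] (or plain data.frames with matching columns; columns are
#'   then treated as continuous).
#' @param classes Subset of `c("linear", "quadratic", "product", "hinge")`.
#' @param n_hinge_knots Hinge knots per variable (used only with `"hinge"`).
#' @return A `maxent_features` object: feature matrix `X` (presence rows
#'   first), logical `presence`, the definition table `defs`, the combined
#'   raw `env` and per-variable `kind`.
#' @export
build_features <- function(env_presence, env_background,
                           classes = c("linear", "quadratic"),
                           n_hinge_knots = 5) {
  classes <- match.arg(classes, c("linear", "quadratic", "product", "hinge"),
                       several.ok = TRUE)
  if (!identical(names(env_presence), names(env_background)))
    stop("presence and background environmental columns differ", call. = FALSE)
  kinds <- env_kinds(env_presence)
  env_all <- rbind(as.data.frame(env_presence), as.data.frame(env_background))
  rownames(env_all) <- NULL
  presence <- c(rep(TRUE, nrow(env_presence)), rep(FALSE, nrow(env_background)))
  defs <- .feature_defs(env_all, kinds, classes, n_hinge_knots,
                        presence_rows = which(presence))
  X <- apply_features(defs, env_all)
  structure(list(X = X, presence = presence, defs = defs, env = env_all,
                 kind = kinds, classes = classes),
            class = "maxent_features")
}

#' @export
print.maxent_features <- function(x, ...) {
  cat(sprintf("<maxent_features> %d presence + %d background rows, %d features (%s)\n",
              sum(x$presence), sum(!x$presence), ncol(x$X),
              paste(x$classes, collapse = "+")))
  invisible(x)
}
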