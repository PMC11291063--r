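## Score-distribution fits, significance thresholds, funnel regions,
## clinical-group summaries.

#' Fit a Gaussian or two-component Gaussian mixture to scores
#'
#' Maximum-likelihood fit of the score distribution. With one component
#' the fit is closed form (sample mean and ML standard deviation). With
#' two components the fit runs expectation-maximization with
#' k-means-style initialization, a `1e-8` tolerance on the log-likelihood,
#' at most 500 iterations, and the best of `n_restarts` seeded restarts.
#' The wild-type-centered component is the one whose mean is closest to
#' 0, and the significance thresholds are `mu_wt +/- z * sd_wt`
#' (`z = 2`: "more than two standard deviations" from the wild-type
#' mean).
#'
#' @param scores Numeric vector of finite scores (>= 50 required).
#' @param n_components 1 or 2.
#' @param seed Integer seed for the restarts.
#' @param z Threshold width in wild-type component standard deviations.
#' @param max_iter,tol,n_restarts EM controls.
#' @return Object of class `mixture_fit`: `n_components`, `weight`,
#'   `mean`, `sd` (per component), `wt_component`, `lo`, `hi`, `loglik`,
#'   `loglik_trace`, `converged`, `n_iter`, `n_obs`, `z`.
#' @export
fit_score_distribution <- function(scores, n_components = 1L, seed = 1L,
                                   z = 2, max_iter = 500L, tol = 1e-8,
                                   n_restarts = 10L) {
  x <- scores[is.finite(scores)]
  if (length(x) < 50L) stop("need >= 50 finite scores to fit")
  if (!n_components %in% c(1L, 2L)) stop("n_components must be 1 or 2")
  if (stats::sd(x) == 0) stop("degenerate input: all scores equal")

  if (n_components == 1L) {
    mu <- mean(x)
    sigma <- sqrt(mean((x - mu)^2))
    ll <- sum(stats::dnorm(x, mu, sigma, log = TRUE))
    fit <- list(n_components = 1L, weight = 1, mean = mu, sd = sigma,
                loglik = ll, loglik_trace = ll, converged = TRUE,
                n_iter = 0L)
  } else {
    fit <- em_best_of(x, seed = seed, max_iter = max_iter, tol = tol,
                      n_restarts = n_restarts)
  }
  wt <- which.min(abs(fit$mean))
  fit$wt_component <- wt
  fit$lo <- fit$mean[wt] - z * fit$sd[wt]
  fit$hi <- fit$mean[wt] + z * fit$sd[wt]
  fit$z <- z
  fit$n_obs <- length(x)
  class(fit) <- "mixture_fit"
  fit
}

## Best-of-restarts EM for a 2-component 1-d Gaussian mixture.
em_best_of <- function(x, seed, max_iter, tol, n_restarts) {
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    km <- tryCatch(stats::kmeans(x, centers = 2L, nstart = 1L),
                   error = function(e) NULL)
    if (is.null(km)) {
      mu0 <- sample(x, 2L)
      init <- list(w = c(0.5, 0.5), mu = mu0, s = rep(stats::sd(x), 2L))
    } else {
      s0 <- vapply(1:2, function(k) stats::sd(x[km$cluster == k]), numeric(1))
      s0[!is.finite(s0) | s0 < 1e-3] <- max(stats::sd(x) / 10, 1e-3)
      init <- list(w = as.numeric(table(factor(km$cluster, 1:2))) / length(x),
                   mu = as.numeric(km$centers), s = s0)
    }
    cand <- em_gaussian2(x, init, max_iter = max_iter, tol = tol)
    if (!is.null(cand) && (is.null(best) || cand$loglik > best$loglik)) {
      best <- cand
    }
  }
  if (is.null(best)) stop("EM failed in every restart")
  best
}

## EM iterations; responsibilities in log space for stability.
em_gaussian2 <- function(x, init, max_iter, tol) {
  w <- init$w
  mu <- init$mu
  s <- pmax(init$s, 1e-6)
  n <- length(x)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    l1 <- log(w[1]) + stats::dnorm(x, mu[1], s[1], log = TRUE)
    l2 <- log(w[2]) + stats::dnorm(x, mu[2], s[2], log = TRUE)
    m <- pmax(l1, l2)
    lse <- m + log(exp(l1 - m) + exp(l2 - m))
    ll <- sum(lse)
    trace <- c(trace, ll)
    if (it > 1L && abs(ll - trace[it - 1L]) < tol) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    g1 <- exp(l1 - lse)
    n1 <- sum(g1)
    n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) return(NULL)  # component collapsed
    w <- c(n1, n2) / n
    mu <- c(sum(g1 * x) / n1, sum((1 - g1) * x) / n2)
    s <- sqrt(c(sum(g1 * (x - mu[1])^2) / n1,
                sum((1 - g1) * (x - mu[2])^2) / n2))
    if (any(!is.finite(s)) || any(s < 1e-8)) return(NULL)  # degenerate
  }
  list(n_components = 2L, weight = w, mean = mu, sd = s,
       loglik = trace[length(trace)], loglik_trace = trace,
       converged = converged, n_iter = it)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit (%d component%s, n = %d)\n",
              x$n_components, if (x$n_components > 1) "s" else "", x$n_obs))
  for (k in seq_len(x$n_components)) {
    cat(sprintf("  comp %d: weight %.3f, mean %+.3f, sd %.3f%s\n",
                k, x$weight[k], x$mean[k], x$sd[k],
                if (k == x$wt_component) "  [wild-type-centered]" else ""))
  }
  cat(sprintf("  thresholds (mean +/- %g sd): [%.3f, %.3f]\n", x$z, x$lo, x$hi))
  cat(sprintf("  loglik %.2f, %sconverged in %d iterations\n",
              x$loglik, if (x$converged) "" else "NOT ", x$n_iter))
  invisible(x)
}

#' Call variants up / neutral / down against a fitted distribution
#'
#' A variant is `up` when its score is strictly above the fit's `hi`
#' threshold and `down` when strictly below `lo` ("more than" z standard
#' deviations from the wild-type-centered mean); a score exactly at a
#' threshold is `neutral`. Missing scores stay `missing`.
#'
#' @param scores Numeric vector (may contain `NA`) or a
#'   [average_scores()] table.
#' @param fit A [fit_score_distribution()] result.
#' @param allow_unconverged Proceed with a non-converged fit?
#' @return Character vector of calls, or the score table with a `call`
#'   column appended.
#' @export
significance_calls <- function(scores, fit, allow_unconverged = FALSE) {
  if (!fit$converged && !allow_unconverged) {
    stop("fit did not converge; pass allow_unconverged = TRUE to override")
  }
  is_table <- is.data.frame(scores)
  x <- if (is_table) scores$score else scores
  call <- rep("missing", length(x))
  ok <- !is.na(x)
  call[ok] <- ifelse(x[ok] > fit$hi, "up",
                     ifelse(x[ok] < fit$lo, "down", "neutral"))
  if (is_table) {
    scores$call <- call
    scores
  } else {
    call
  }
}

## Funnel region lookup: rows = FL call, cols = PTP call.
## Region I also covers (FL neutral, PTP down): variants whose reduced
## intrinsic activity is fully compensated by released auto-inhibition.
region_map <- function() {
  m <- matrix("unclassified", 4, 4,
              dimnames = list(c("up", "neutral", "down", "missing"),
                              c("up", "neutral", "down", "missing")))
  m["up", "up"] <- "IV"
  m["up", "neutral"] <- "I"
  m["up", "down"] <- "I"
  m["neutral", "up"] <- "IV"
  m["neutral", "neutral"] <- "neutral"
  m["neutral", "down"] <- "I"
  m["down", "up"] <- "unclassified"  # no mechanistic region defined
  m["down", "neutral"] <- "III"
  m["down", "down"] <- "II"
  m
}

#' Classify shared variants into funnel regions
#'
#' Maps each (full-length call, PTP-domain call) pair to a mechanistic
#' region of the joint score distribution:
#' * **I** - auto-inhibition disrupted: activating in FL while neutral or
#'   deactivating in PTP (including PTP-down/FL-neutral variants whose
#'   catalytic loss is compensated by release).
#' * **II** - catalytically dead: deactivating in both constructs.
#' * **III** - closed-state stabilized: deactivating in FL only.
#' * **IV** - intrinsic catalytic gain: activating in PTP with neutral or
#'   activating FL effect.
#' * **neutral** - both neutral; **unclassified** - any pair involving a
#'   missing call, or the mechanistically undefined (FL down, PTP up).
#'
#' @param fl_calls,ptp_calls Character vectors of calls
#'   (`up`/`neutral`/`down`/`missing`), aligned by variant.
#' @param variant_id Optional ids for the output.
#' @return data.frame: `variant_id` (if given), `fl_call`, `ptp_call`,
#'   `region`.
#' @export
classify_regions <- function(fl_calls, ptp_calls, variant_id = NULL) {
  if (length(fl_calls) != length(ptp_calls)) {
    stop("fl_calls and ptp_calls must align")
  }
  lv <- c("up", "neutral", "down", "missing")
  if (!all(fl_calls %in% lv) || !all(ptp_calls %in% lv)) {
    stop("calls must be one of: ", paste(lv, collapse = ", "))
  }
  m <- region_map()
  region <- m[cbind(fl_calls, ptp_calls)]
  out <- data.frame(fl_call = fl_calls, ptp_call = ptp_calls,
                    region = region, stringsAsFactors = FALSE)
  if (!is.null(variant_id)) out <- cbind(variant_id = variant_id, out)
  out
}

#' Summarize scores by annotation group
#'
#' Joins a clinical-annotation table onto a score table by `variant_id`
#' and reports the per-group member count and mean score, computed over
#' unique variants (a variant annotated by several sources counts once
#' per group). Variants with no annotation form the `background` group.
#' Annotations referencing unknown variants are skipped with a warning.
#'
#' @param scores A [average_scores()] table.
#' @param annotations data.frame with `variant_id` and the grouping
#'   field (see [emit_annotations()]).
#' @param grouping Annotation column to group by.
#' @return data.frame: `group`, `n`, `mean_score`; attribute
#'   `member_scores` holds the per-group score vectors.
#' @export
group_summaries <- function(scores, annotations, grouping = "disease_group") {
  if (!grouping %in% names(annotations)) {
    stop("annotation table has no column '", grouping, "'")
  }
  known <- annotations$variant_id %in% scores$variant_id
  if (any(!known)) {
    warning(sum(!known), " annotation row(s) reference unknown variants; skipped")
    annotations <- annotations[known, , drop = FALSE]
  }
  ann <- unique(annotations[c("variant_id", grouping)])
  groups <- split(ann$variant_id, ann[[grouping]])
  groups$background <- setdiff(scores$variant_id, annotations$variant_id)
  members <- lapply(groups, function(ids) {
    s <- scores$score[match(ids, scores$variant_id)]
    s[!is.na(s)]
  })
  members <- members[vapply(members, length, integer(1)) > 0L]
  out <- data.frame(
    group = names(members),
    n = vapply(members, length, integer(1)),
    mean_score = vapply(members, mean, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "member_scores") <- members
  out
}

#' Joined FL-vs-PTP funnel table
#'
#' One row per variant of the shared (PTP-window) space present in both
#' score tables: both scores, the funnel region, and collapsed clinical
#' annotations. Variants missing from either table are excluded and
#' tallied in the `n_excluded` attribute.
#'
#' @param fl_scores,ptp_scores [average_scores()] tables for the
#'   full-length and PTP-domain selections.
#' @param regions Optional [classify_regions()] output keyed by
#'   `variant_id`.
#' @param annotations Optional annotation table (see
#'   [emit_annotations()]).
#' @return data.frame: `variant_id`, `position`, `wt_aa`, `mut_aa`,
#'   `fl_score`, `ptp_score`, `region`, `disease_groups`.
#' @export
funnel_table <- function(fl_scores, ptp_scores, regions = NULL,
                         annotations = NULL) {
  shared <- intersect(fl_scores$variant_id, ptp_scores$variant_id)
  fl <- fl_scores[match(shared, fl_scores$variant_id), ]
  pt <- ptp_scores[match(shared, ptp_scores$variant_id), ]
  out <- data.frame(
    variant_id = shared,
    position = fl$position,
    wt_aa = fl$wt_aa,
    mut_aa = fl$mut_aa,
    fl_score = fl$score,
    ptp_score = pt$score,
    stringsAsFactors = FALSE
  )
  out$region <- if (is.null(regions)) {
    NA_character_
  } else {
    regions$region[match(shared, regions$variant_id)]
  }
  out$disease_groups <- if (is.null(annotations)) {
    NA_character_
  } else {
    ann <- split(annotations$disease_group, annotations$variant_id)
    vapply(shared, function(v) {
      g <- unique(ann[[v]])
      if (is.null(g)) NA_character_ else paste(sort(g), collapse = ";")
    }, character(1), USE.NAMES = FALSE)
  }
  attr(out, "n_excluded") <- length(union(fl_scores$variant_id,
                                          ptp_scores$variant_id)) -
    length(shared)
  out
}
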