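#' Logistic effect size of the per-sample distance statistic
#'
#' Fits `status ~ D` by maximum-likelihood logistic regression. The odds
#' ratio `exp(slope)` is the multiplicative change in disease odds per unit
#' increase in D; `OR_p` is the two-sided Wald p-value for the slope.
#' Complete or quasi-complete separation is reported via the `separation`
#' flag (the Wald p is meaningless there) rather than silently, keeping the
#' plain-logistic semantics.
#'
#' @param profile A `poda_profile` tibble, or a numeric vector of per-sample
#'   D values.
#' @param status Class labels, required when `profile` is a bare vector.
#' @return A one-row tibble: `OR`, `OR_p`, `slope`, `converged`,
#'   `separation`.
#' @examples
#' logistic_odds_ratio(c(-2, -1, 0, 1, 2, 3),
#'                     c(rep("control", 3), rep("case", 3)))
#' @export
logistic_odds_ratio <- function(profile, status = NULL) {
  if (is.data.frame(profile)) {
    D <- profile$D
    if (is.null(status)) status <- profile$status
  } else {
    D <- profile
  }
  if (is.null(status)) stop("`status` required", call. = FALSE)
  status <- as_status(status, length(D))
  if (!all(is.finite(D))) stop("non-finite D values", call. = FALSE)
  y <- as.integer(status == "case")
  if (stats::sd(D) == 0) {
    # a constant predictor carries no information: unit odds ratio
    return(tibble::tibble(OR = 1, OR_p = 1, slope = 0,
                          converged = TRUE, separation = FALSE))
  }
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ D, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  slope <- unname(stats::coef(fit)["D"])
  sm <- summary(fit)$coefficients
  or_p <- if ("D" %in% rownames(sm)) unname(sm["D", "Pr(>|z|)"]) else NA_real_
  separation <- isTRUE(sep_warn || (!is.na(slope) && abs(slope) > 15))
  if (separation) {
    warning("possible complete separation in the logistic fit; the Wald ",
            "p-value is unreliable", call. = FALSE)
  }
  tibble::tibble(
    OR = exp(slope),
    OR_p = or_p,
    slope = slope,
    converged = fit$converged,
    separation = separation
  )
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment: with the p-values sorted ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} m \, p_{(j)} / j} (capped at 1), mapped
#' back to the input order.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Vector of q-values in input order, elementwise at least `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  m <- length(p_values)
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p_values[o]))[ro]
  q
}

#' Greedy redundancy culling of overlapping pathways
#'
#' Pathways probing largely the same SNPs are redundant. Walking the
#' pathways in some order, a pathway is removed when it shares strictly more
#' than `threshold` of its SNPs with an already-retained pathway (overlap =
#' shared / size of the smaller set, so a subset pathway is always caught).
#' Because the outcome depends on the walk order, the pass is repeated over
#' `n_orders` random orders plus the score-descending order, and the modal
#' retained set is reported (ties resolved toward the score-descending
#' outcome).
#'
#' @param snp_sets Named list: pathway id -> SNP id vector (e.g. the
#'   `snp_sets` element of a [select_representative_snps()] result).
#' @param scores Named numeric ranking (larger = kept earlier in the
#'   score-descending order), e.g. distinction scores.
#' @param threshold Overlap fraction above which a pathway is culled
#'   (default 0.60; strictly greater removes).
#' @param n_orders Number of random orders tried in addition to the
#'   score-descending order (default 25).
#' @param seed Optional RNG seed for the random orders.
#' @return An object of class `poda_culling`: list with `retained`
#'   (character), `removed` (tibble `pathway`, `partner`, `overlap`),
#'   `modal_frequency` (share of orders giving the modal set) and
#'   `n_orders_total`.
#' @export
pathway_overlap_cull <- function(snp_sets, scores, threshold = 0.60,
                                 n_orders = 25, seed = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  ids <- names(snp_sets)
  if (is.null(ids)) stop("`snp_sets` must be a named list", call. = FALSE)
  missing_sc <- setdiff(ids, names(scores))
  if (length(missing_sc)) {
    stop("missing score(s) for: ", paste(missing_sc, collapse = ", "),
         call. = FALSE)
  }
  overlap <- function(a, b) {
    length(intersect(a, b)) / min(length(a), length(b))
  }
  greedy <- function(order_ids) {
    retained <- character(0)
    removed <- list()
    for (pw in order_ids) {
      ov <- vapply(retained, function(r) overlap(snp_sets[[pw]], snp_sets[[r]]),
                   numeric(1))
      hit <- which(ov > threshold)
      if (length(hit)) {
        k <- hit[which.max(ov[hit])]
        removed[[pw]] <- list(partner = retained[k], overlap = ov[k])
      } else {
        retained <- c(retained, pw)
      }
    }
    list(retained = retained, removed = removed)
  }
  score_order <- ids[order(-scores[ids], ids)]
  if (!is.null(seed)) set.seed(seed)
  orders <- c(list(score_order),
              replicate(n_orders, sample(ids), simplify = FALSE))
  outs <- lapply(orders, greedy)
  keys <- vapply(outs, function(o) paste(sort(o$retained), collapse = "\r"),
                 character(1))
  tab <- table(keys)
  modal_key <- names(tab)[tab == max(tab)]
  # ties between equally frequent sets resolve toward the score-order result
  chosen_key <- if (keys[1] %in% modal_key) keys[1] else modal_key[1]
  chosen <- outs[[match(chosen_key, keys)]]
  removed_tbl <- if (length(chosen$removed)) {
    tibble::tibble(
      pathway = names(chosen$removed),
      partner = unname(vapply(chosen$removed, `[[`, character(1), "partner")),
      overlap = unname(vapply(chosen$removed, `[[`, numeric(1), "overlap"))
    )
  } else {
    tibble::tibble(pathway = character(), partner = character(),
                   overlap = numeric())
  }
  structure(
    list(retained = chosen$retained,
         removed = removed_tbl,
         modal_frequency = max(tab) / length(keys),
         n_orders_total = length(keys)),
    class = "poda_culling"
  )
}

#' @export
print.poda_culling <- function(x, ...) {
  cat("<poda_culling> retained ", length(x$retained), " pathway(s), removed ",
      nrow(x$removed), "; modal outcome in ",
      format(round(100 * x$modal_frequency, 1)), "% of ",
      x$n_orders_total, " orders\n", sep = "")
  invisible(x)
}

#' Correlation of per-sample distance statistics across pathways
#'
#' Pearson correlation between the per-sample D vectors of every pathway
#' pair, over identical samples. High correlation means two pathways reflect
#' the same genetic variation in the same samples.
#'
#' @param profiles Named list of `poda_profile` tibbles over the same
#'   samples, or a numeric matrix (samples x pathways).
#' @return Symmetric correlation matrix with unit diagonal. Zero-variance
#'   profiles give `NA` entries with a warning, never a silent 0.
#' @export
d_correlation_matrix <- function(profiles) {
  if (is.list(profiles) && !is.data.frame(profiles)) {
    if (length(profiles) < 2L) stop("need at least 2 profiles", call. = FALSE)
    samp <- profiles[[1]]$sample
    for (p in profiles) {
      if (!identical(p$sample, samp)) {
        stop("profiles must cover identical samples in identical order",
             call. = FALSE)
      }
    }
    m <- vapply(profiles, function(p) p$D, numeric(length(samp)))
    rownames(m) <- samp
  } else {
    m <- as.matrix(profiles)
    if (ncol(m) < 2L) stop("need at least 2 profiles", call. = FALSE)
  }
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance profile(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "),
            "; correlations set to NA", call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(m))
  diag(r) <- 1
  r
}
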