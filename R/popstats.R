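# Rank tests, multiple-testing, directional binomial tests and the
# African / non-African copy-number differentiation workflow.

#' Mann-Whitney U test
#'
#' Exact two-sided P by enumeration of all group assignments when the total
#' sample size is at most `exact_max` (ties handled through average ranks);
#' otherwise the normal approximation with tie-corrected variance and
#' continuity correction.
#'
#' @param values_a,values_b numeric vectors (nonempty).
#' @param exact_max largest total n for exact enumeration (default 12).
#' @return list with `U` (statistic for group A), `p_value`, `method`.
#' @export
mannWhitney <- function(values_a, values_b, exact_max = 12) {
    na <- length(values_a); nb <- length(values_b)
    if (!na || !nb) stop("both groups must be nonempty")
    pool <- c(values_a, values_b)
    rk <- rank(pool)
    U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
    n <- na + nb
    if (n <= exact_max) {
        combs <- utils::combn(n, na)
        us <- colSums(matrix(rk[combs], nrow = na)) - na * (na + 1) / 2
        mu <- na * nb / 2
        # two-sided: outcomes at least as far from the mean as observed
        p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
        list(U = U, p_value = p, method = "exact")
    } else {
        mu <- na * nb / 2
        ties <- table(rk)
        sig2 <- na * nb / 12 *
            ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
        if (sig2 == 0) return(list(U = U, p_value = 1, method = "approx"))
        z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
        p <- min(1, 2 * stats::pnorm(-abs(z)))
        list(U = U, p_value = p, method = "approx")
    }
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (monotone, capped at 1).
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
bhAdjust <- function(p_values) {
    if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p_values, method = "BH")
}

#' One-sided exact binomial test toward the observed direction
#'
#' With `k` of `n` effects in one direction under a fair-coin null, the
#' P value is the upper-tail probability of at least `max(k, n - k)`
#' successes; symmetric in `k` and `n - k`.
#'
#' @param k number of effects in the majority direction (0..n).
#' @param n number of effects.
#' @return the one-sided exact P value.
#' @export
binomialDirection <- function(k, n) {
    if (n == 0) stop("binomial test undefined for n = 0")
    if (k < 0 || k > n) stop("k must lie in [0, n]")
    kk <- max(k, n - k)
    stats::pbinom(kk - 1, n, 0.5, lower.tail = FALSE)
}

#' African vs non-African copy-number differentiation
#'
#' Eligibility: a family passes in a group when its dispersion index is at
#' least `min_dispersion` and its mean copy number exceeds `min_mean_cn`;
#' a family is tested when it passes in the African or the non-African
#' samples. Eligible families are compared across groups by Mann-Whitney,
#' BH-adjusted over eligible families; significant families (adjusted
#' P <= `alpha`, or strictly < with `strict_alpha = TRUE`) get a direction
#' from the group means, summarised with [binomialDirection()]. When a
#' replication cohort `cn2` is given, a significant family is `replicated`
#' iff it is significant there with the same direction.
#'
#' @param cn family-level [CopyNumberExperiment-class].
#' @param labels data.frame with `sample_id, superpopulation` covering the
#'   columns of `cn` (a full label table also works).
#' @param min_dispersion eligibility dispersion bound (default 0.1, >=).
#' @param min_mean_cn eligibility mean-CN bound (default 2, strict >).
#' @param alpha significance level on adjusted P (default 0.05).
#' @param strict_alpha require adjusted P strictly below alpha (default
#'   `FALSE`, i.e. <=).
#' @param cn2 optional replication [CopyNumberExperiment-class].
#' @param labels2 labels for `cn2` (defaults to `labels`).
#' @return list with `results` (per-family data.frame: statistic, raw and
#'   adjusted P, direction, significant, replicated), `summary` (list:
#'   n_eligible, n_significant, n_afr_higher, binomial_p, prop_afr_higher,
#'   n_replicated).
#' @export
cnDifferentiation <- function(cn, labels, min_dispersion = 0.1,
                              min_mean_cn = 2.0, alpha = 0.05,
                              strict_alpha = FALSE, cn2 = NULL,
                              labels2 = labels) {
    res <- .diffOneCohort(cn, labels, min_dispersion, min_mean_cn, alpha,
                          strict_alpha)
    results <- res$results
    results$replicated <- NA
    if (!is.null(cn2)) {
        res2 <- .diffOneCohort(cn2, labels2, min_dispersion, min_mean_cn,
                               alpha, strict_alpha = TRUE)
        r2 <- res2$results
        idx <- match(results$family_id, r2$family_id)
        results$replicated <- results$significant &
            !is.na(idx) & r2$significant[idx] &
            r2$direction[idx] == results$direction
    }
    sig <- results[results$significant, , drop = FALSE]
    k <- sum(sig$direction == "AFR_higher")
    nsig <- nrow(sig)
    list(results = results,
         summary = list(
             n_eligible = sum(!is.na(results$p_value)),
             n_significant = nsig,
             n_afr_higher = k,
             prop_afr_higher = if (nsig) k / nsig else NA_real_,
             binomial_p = if (nsig) binomialDirection(k, nsig) else NA_real_,
             n_replicated = if (!is.null(cn2)) sum(results$replicated,
                                                   na.rm = TRUE) else NA))
}

.diffOneCohort <- function(cn, labels, min_dispersion, min_mean_cn, alpha,
                           strict_alpha) {
    m <- copyNumber(cn)
    sup <- labels$superpopulation[match(colnames(m), labels$sample_id)]
    if (anyNA(sup)) stop("sample(s) of the CN matrix missing from labels")
    afr <- m[, sup == "AFR", drop = FALSE]
    non <- m[, sup == "nonAFR", drop = FALSE]
    if (ncol(afr) < 2 || ncol(non) < 2)
        stop("need at least two samples per group")
    passes <- function(g) {
        mu <- rowMeans(g)
        dv <- apply(g, 1, stats::var)
        di <- ifelse(mu > 0, dv / mu, NA_real_)
        !is.na(di) & di >= min_dispersion & mu > min_mean_cn
    }
    eligible <- passes(afr) | passes(non)
    if (!any(eligible)) {
        warning("no eligible families")
        return(list(results = data.frame(
            family_id = rownames(m), statistic = NA_real_,
            p_value = NA_real_, p_adjusted = NA_real_,
            direction = NA_character_, significant = FALSE)))
    }
    fam <- rownames(m)
    stat <- p <- rep(NA_real_, length(fam))
    dirn <- rep(NA_character_, length(fam))
    for (i in which(eligible)) {
        mw <- mannWhitney(afr[i, ], non[i, ])
        stat[i] <- mw$U
        p[i] <- mw$p_value
        dirn[i] <- if (mean(afr[i, ]) >= mean(non[i, ])) "AFR_higher"
                   else "nonAFR_higher"
    }
    padj <- rep(NA_real_, length(fam))
    padj[eligible] <- bhAdjust(p[eligible])
    sig <- !is.na(padj) &
        (if (strict_alpha) padj < alpha else padj <= alpha)
    list(results = data.frame(
        family_id = fam, statistic = stat, p_value = p, p_adjusted = padj,
        direction = dirn, significant = sig, row.names = NULL,
        stringsAsFactors = FALSE))
}
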