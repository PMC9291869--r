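## Differential expression (Wilcoxon rank-sum, Bonferroni) and
## differential co-expression (Pearson matrices, Steiger matrix-equality
## chi-square, pairwise two-sample Fisher r-to-z) between affected and
## unaffected samples, per compartment.

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided Mann-Whitney U for group \code{a} against group \code{b}.
#' The p-value comes from the exact null distribution when the combined
#' sample size is at most 12 and there are no ties, and otherwise from the
#' normal approximation with tie-corrected variance and continuity
#' correction (the same conventions as \code{\link[stats]{wilcox.test}},
#' which performs the computation).
#'
#' @param a,b numeric vectors, each non-empty.
#' @return list with \code{U} (rank-sum statistic for \code{a}) and
#'   \code{p} (two-sided p-value).
#' @export
rankSumTest <- function(a, b) {
    if (!length(a) || !length(b)) stop("both groups must be non-empty")
    n <- length(a) + length(b)
    ties <- anyDuplicated(c(a, b)) > 0L
    ht <- suppressWarnings(
        stats::wilcox.test(a, b, alternative = "two.sided",
                           exact = (n <= 12L && !ties), correct = TRUE))
    list(U = unname(ht$statistic), p = ht$p.value)
}

#' Bonferroni correction
#'
#' @param p vector of raw p-values in (0, 1].
#' @param m family size, at least \code{length(p)}; defaults to
#'   \code{length(p)}.
#' @return vector of \code{min(1, m * p)}.
#' @export
bonferroni <- function(p, m = length(p)) {
    if (m < length(p))
        stop("family size m must be >= number of p-values")
    if (length(p) == 0L) return(numeric(0))
    stats::p.adjust(p, method = "bonferroni", n = m)
}

#' Differential expression between affected and unaffected samples
#'
#' Runs, per compartment and per gene, a two-sided Wilcoxon rank-sum test
#' of z-scored expression in affected versus unaffected samples, and
#' reports the mean z difference (affected - unaffected) alongside raw
#' and Bonferroni-corrected p-values. The Bonferroni family is the number
#' of genes tested within one compartment for one map; the family size is
#' recorded in the output. Compartments with an empty affected or
#' unaffected group are flagged untestable rather than fabricated.
#'
#' @param exprZ \linkS4class{BrainExpression} with \code{valueKind}
#'   \code{"z_scored"}, genes in rows.
#' @param cls classification data.frame from
#'   \code{\link{classifySamples}}.
#' @param genes gene symbols to test (rows of \code{exprZ}).
#' @param mapName label of the statistic map, copied into the output.
#' @return data.frame with one row per gene x compartment:
#'   \code{map_name}, \code{compartment}, \code{gene}, group sizes,
#'   \code{rank_sum_U}, \code{mean_diff_z}, \code{p_raw}, \code{m_tests},
#'   \code{p_bonf}, \code{significant}, \code{untestable}.
#' @export
differentialExpression <- function(exprZ, cls, genes, mapName = "map") {
    if (valueKind(exprZ) != "z_scored")
        stop("differential expression expects z-scored values")
    missing <- setdiff(genes, rownames(exprZ))
    if (length(missing))
        stop("gene(s) absent from expression matrix: ",
             paste(missing, collapse = ", "))
    m <- exprValues(exprZ)
    cls <- cls[!cls$excluded & cls$sample_id %in% colnames(m), ,
               drop = FALSE]
    res <- list()
    for (comp in c("subcortex", "cortex")) {
        aff <- cls$sample_id[cls$compartment == comp &
                             cls$label == "affected"]
        una <- cls$sample_id[cls$compartment == comp &
                             cls$label == "unaffected"]
        testable <- length(aff) > 0L && length(una) > 0L
        rows <- lapply(genes, function(g) {
            if (testable) {
                ts <- rankSumTest(m[g, aff], m[g, una])
                data.frame(map_name = mapName, compartment = comp,
                           gene = g, n_affected = length(aff),
                           n_unaffected = length(una),
                           rank_sum_U = ts$U,
                           mean_diff_z = mean(m[g, aff]) -
                                         mean(m[g, una]),
                           p_raw = ts$p, stringsAsFactors = FALSE)
            } else {
                data.frame(map_name = mapName, compartment = comp,
                           gene = g, n_affected = length(aff),
                           n_unaffected = length(una),
                           rank_sum_U = NA_real_,
                           mean_diff_z = NA_real_, p_raw = NA_real_,
                           stringsAsFactors = FALSE)
            }
        })
        block <- do.call(rbind, rows)
        block$m_tests <- length(genes)
        block$p_bonf <- if (testable)
            bonferroni(block$p_raw, length(genes)) else NA_real_
        block$significant <- !is.na(block$p_bonf) & block$p_bonf < 0.05
        block$untestable <- !testable
        res[[comp]] <- block
    }
    do.call(rbind, c(res, make.row.names = FALSE))
}

#' Pearson correlation matrix with per-pair p-values
#'
#' Computes the gene-by-gene Pearson correlation matrix over a sample
#' subset, with two-sided per-pair p-values from the t transform
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on n - 2 degrees of freedom,
#' Bonferroni-corrected over the k(k-1)/2 pairs.
#'
#' @param exprZ \linkS4class{BrainExpression}, genes in rows.
#' @param sampleSubset sample ids (columns) to use; at least 4.
#' @param genes gene symbols (rows) to correlate.
#' @return list with \code{R} (correlation matrix), \code{p_raw} and
#'   \code{p_bonf} (per-pair p-value matrices, NA diagonal), \code{n}.
#' @export
pearsonMatrix <- function(exprZ, sampleSubset, genes) {
    sampleSubset <- intersect(sampleSubset, colnames(exprZ))
    n <- length(sampleSubset)
    if (n < 4L) stop("need at least 4 samples for a correlation matrix")
    m <- exprValues(exprZ)[genes, sampleSubset, drop = FALSE]
    sds <- apply(m, 1L, sd)
    if (any(sds == 0))
        stop("zero-variance gene(s) within subset: ",
             paste(genes[sds == 0], collapse = ", "))
    R <- cor(t(m))
    tstat <- R * sqrt((n - 2) / pmax(1 - R^2, .Machine$double.eps))
    p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    diag(p) <- NA_real_
    k <- length(genes)
    npairs <- k * (k - 1) / 2
    pb <- p * npairs
    pb[!is.na(pb) & pb > 1] <- 1
    list(R = R, p_raw = p, p_bonf = pb, n = n)
}

#' Steiger test for equality of two correlation matrices
#'
#' Normal-theory chi-square test: with \eqn{z_{ij} = \mathrm{atanh}(r_{ij})},
#' \deqn{\chi^2 = \sum_{i<j} \frac{(z^{(1)}_{ij} - z^{(2)}_{ij})^2}
#'   {1/(n_1-3) + 1/(n_2-3)}}
#' on k(k-1)/2 degrees of freedom.
#'
#' @param R1,R2 correlation matrices over the same genes in the same
#'   order.
#' @param n1,n2 group sizes, each > 3.
#' @return list with \code{chi2}, \code{df}, \code{p}.
#' @export
steigerMatrixTest <- function(R1, n1, R2, n2) {
    if (!identical(dim(R1), dim(R2)))
        stop("correlation matrices must have identical dimensions")
    if (n1 <= 3 || n2 <= 3) stop("group sizes must exceed 3")
    low <- lower.tri(R1)
    r1 <- R1[low]; r2 <- R2[low]
    if (any(abs(r1) >= 1) || any(abs(r2) >= 1))
        stop("off-diagonal |r| = 1: Fisher z transform diverges")
    z1 <- atanh(r1); z2 <- atanh(r2)
    vsum <- 1 / (n1 - 3) + 1 / (n2 - 3)
    chi2 <- sum((z1 - z2)^2) / vsum
    df <- length(r1)
    list(chi2 = chi2, df = as.integer(df),
         p = pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Two-sample comparison of correlation coefficients (Fisher r-to-z)
#'
#' \deqn{z = \frac{\mathrm{atanh}(r_1) - \mathrm{atanh}(r_2)}
#'   {\sqrt{1/(n_1-3) + 1/(n_2-3)}}}
#' with a two-tailed standard-normal p-value.
#'
#' @param r1,r2 correlation coefficients, |r| < 1.
#' @param n1,n2 group sizes, each > 3.
#' @return list with \code{z} and \code{p}.
#' @export
fisherZCompare <- function(r1, n1, r2, n2) {
    if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
    if (n1 <= 3 || n2 <= 3) stop("group sizes must exceed 3")
    z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
    list(z = z, p = 2 * pnorm(abs(z), lower.tail = FALSE))
}

#' Differential co-expression contrast for a focus gene
#'
#' Builds the Pearson correlation matrices of the genes of interest in
#' affected and unaffected samples of one compartment, tests matrix
#' equality with the Steiger chi-square, then contrasts the focus gene's
#' pairwise correlations between the groups with two-sample Fisher r-to-z
#' tests. Before the contrast, focus-gene pairs whose correlation is not
#' Bonferroni-significant are filtered out: under the default rule
#' \code{"either"} a pair is retained when its correlation is significant
#' in at least one group; under \code{"both"} only when significant in
#' both. Fisher p-values are Bonferroni-corrected over the retained
#' pairs.
#'
#' @param exprZ z-scored \linkS4class{BrainExpression}, genes in rows.
#' @param cls classification data.frame from
#'   \code{\link{classifySamples}}.
#' @param genes gene symbols to correlate.
#' @param focusGene the gene whose pairs are contrasted (must be in
#'   \code{genes}).
#' @param compartment \code{"subcortex"} (default) or \code{"cortex"}.
#' @param filterRule \code{"either"} (default) or \code{"both"}.
#' @param gateOnSteiger when TRUE, pairwise contrasts are only performed
#'   if the Steiger matrix test is significant at 0.05; off by default.
#' @param mapName map label copied into the pair table.
#' @return A \linkS4class{CorrelationComparison}.
#' @export
coexpressionContrast <- function(exprZ, cls, genes, focusGene = "OXTR",
                                 compartment = "subcortex",
                                 filterRule = c("either", "both"),
                                 gateOnSteiger = FALSE, mapName = "map") {
    filterRule <- match.arg(filterRule)
    if (!focusGene %in% genes)
        stop("focusGene must be one of the genes of interest")
    cls <- cls[!cls$excluded & cls$compartment == compartment, ,
               drop = FALSE]
    aff <- cls$sample_id[cls$label == "affected"]
    una <- cls$sample_id[cls$label == "unaffected"]
    pmA <- pearsonMatrix(exprZ, aff, genes)
    pmU <- pearsonMatrix(exprZ, una, genes)
    st <- steigerMatrixTest(pmA$R, pmA$n, pmU$R, pmU$n)

    others <- setdiff(genes, focusGene)
    retain <- vapply(others, function(g) {
        sigA <- pmA$p_bonf[focusGene, g] < 0.05
        sigU <- pmU$p_bonf[focusGene, g] < 0.05
        if (filterRule == "either") sigA || sigU else sigA && sigU
    }, logical(1))
    if (gateOnSteiger && st$p >= 0.05) retain[] <- FALSE
    kept <- others[retain]

    fisher <- if (length(kept)) {
        rows <- lapply(kept, function(g) {
            fz <- fisherZCompare(pmA$R[focusGene, g], pmA$n,
                                 pmU$R[focusGene, g], pmU$n)
            data.frame(map_name = mapName, compartment = compartment,
                       gene_a = focusGene, gene_b = g,
                       r_affected = pmA$R[focusGene, g],
                       r_unaffected = pmU$R[focusGene, g],
                       z_stat = fz$z, p_raw = fz$p,
                       stringsAsFactors = FALSE)
        })
        out <- do.call(rbind, rows)
        out$m_pairs <- length(kept)
        out$p_bonf <- bonferroni(out$p_raw, length(kept))
        out$significant <- out$p_bonf < 0.05
        out
    } else {
        data.frame(map_name = character(0), compartment = character(0),
                   gene_a = character(0), gene_b = character(0),
                   r_affected = numeric(0), r_unaffected = numeric(0),
                   z_stat = numeric(0), p_raw = numeric(0),
                   m_pairs = integer(0), p_bonf = numeric(0),
                   significant = logical(0))
    }
    new("CorrelationComparison", genes = genes, Raffected = pmA$R,
        Runaffected = pmU$R, n1 = as.integer(pmA$n),
        n2 = as.integer(pmU$n), pairPAffected = pmA$p_bonf,
        pairPUnaffected = pmU$p_bonf, steiger = st, fisher = fisher,
        focusGene = focusGene, filterRule = filterRule)
}
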