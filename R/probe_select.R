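## Probe-to-gene collapse: one representative probe per gene, chosen by
## intensity and optionally validated against RNA-seq from the donor
## subset that has it.

#' Read a probe-to-gene annotation table
#'
#' @param path CSV/TSV with columns \code{probe_id} and \code{gene_symbol};
#'   every probe maps to exactly one gene.
#' @return data.frame with columns \code{probe_id}, \code{gene_symbol}.
#' @export
readProbeMap <- function(path) {
    if (!file.exists(path)) stop("probe map not found: ", path)
    df <- read.csv(path, sep = .detect_delim(path),
                   stringsAsFactors = FALSE)
    if (!all(c("probe_id", "gene_symbol") %in% names(df)))
        stop("probe map must have columns probe_id and gene_symbol")
    df$probe_id <- as.character(df$probe_id)
    df$gene_symbol <- as.character(df$gene_symbol)
    if (anyDuplicated(df$probe_id))
        stop("probe map assigns a probe to more than one gene")
    df[, c("probe_id", "gene_symbol")]
}

#' Select one probe per gene by mean intensity
#'
#' For a gene with several annotated probes, picks the probe whose mean
#' expression across all loaded samples is highest ("intensity" probe
#' selection). Intensity is the arithmetic mean of the probe's row; exact
#' ties are broken toward the lexicographically smallest probe id, so the
#' choice is deterministic and invariant to row/column order.
#'
#' @param expr \linkS4class{BrainExpression} with probes in rows.
#' @param probeMap data.frame with \code{probe_id}, \code{gene_symbol}.
#' @param gene gene symbol to select a probe for.
#' @return one-row data.frame: \code{gene_symbol}, \code{selected_probe},
#'   \code{mean_intensity}.
#' @export
selectProbeByIntensity <- function(expr, probeMap, gene) {
    probes <- probeMap$probe_id[probeMap$gene_symbol == gene]
    probes <- intersect(probes, rownames(expr))
    if (!length(probes))
        stop("no probe for gene ", gene, " present in the expression matrix")
    means <- rowMeans(exprValues(expr)[probes, , drop = FALSE])
    ord <- order(-means, probes)  # ties -> smallest probe id
    data.frame(gene_symbol = gene, selected_probe = probes[ord[1]],
               mean_intensity = unname(means[ord[1]]),
               stringsAsFactors = FALSE)
}

#' Select probes for a set of genes
#'
#' @param expr \linkS4class{BrainExpression} with probes in rows.
#' @param probeMap probe-to-gene annotation.
#' @param genes gene symbols; defaults to all genes in \code{probeMap}.
#' @return data.frame, one row per gene.
#' @export
selectProbes <- function(expr, probeMap, genes = unique(probeMap$gene_symbol)) {
    do.call(rbind, lapply(genes, function(g)
        selectProbeByIntensity(expr, probeMap, g)))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, via Pearson correlation
#' of the rank vectors.
#'
#' @param a,b equal-length finite numeric vectors (length >= 3).
#' @return Spearman's rho in [-1, 1].
#' @export
spearmanRho <- function(a, b) {
    if (length(a) != length(b)) stop("vectors must have equal length")
    if (length(a) < 3L) stop("need at least 3 paired observations")
    if (any(!is.finite(a)) || any(!is.finite(b)))
        stop("inputs must be finite")
    if (var(rank(a)) == 0 || var(rank(b)) == 0)
        stop("rank variance is zero; correlation undefined")
    cor(a, b, method = "spearman")
}

#' Validate a probe selection against RNA-seq
#'
#' For each probe of the gene, computes Spearman's rho between the probe's
#' microarray values and the gene's RNA-seq values over the samples shared
#' by both matrices (restricted to \code{donorSubset} when given; RNA-seq
#' is typically available for two donors only). The selection is
#' \emph{validated} when the intensity-selected probe also attains the
#' maximal rho. A failed validation is reported with a warning, not an
#' error: the intensity-selected probe remains the representative.
#'
#' @param selection one-row data.frame from
#'   \code{\link{selectProbeByIntensity}}.
#' @param expr \linkS4class{BrainExpression}, probes x samples.
#' @param rnaseq \linkS4class{BrainExpression} with \code{valueKind}
#'   \code{"rnaseq"}, genes x samples.
#' @param probeMap probe-to-gene annotation.
#' @param donorSubset optional donor ids restricting the shared samples;
#'   requires donor annotation in \code{colData(expr)}.
#' @return the selection row extended with \code{rnaseq_rho} (rho of the
#'   selected probe), \code{validated} (logical, NA when fewer than 3
#'   shared samples) and attribute \code{"all_rho"} (named rho per probe).
#' @export
validateSelection <- function(selection, expr, rnaseq, probeMap,
                              donorSubset = NULL) {
    gene <- selection$gene_symbol
    probes <- intersect(probeMap$probe_id[probeMap$gene_symbol == gene],
                        rownames(expr))
    shared <- intersect(colnames(expr), colnames(rnaseq))
    if (!is.null(donorSubset)) {
        si <- sampleInfo(expr)
        if (!"donor_id" %in% names(si))
            stop("expr carries no donor annotation; cannot subset donors")
        keep <- rownames(si)[si$donor_id %in% donorSubset]
        shared <- intersect(shared, keep)
    }
    if (!gene %in% rownames(rnaseq))
        stop("gene ", gene, " absent from the RNA-seq matrix")
    if (length(shared) < 3L) {
        warning("validation skipped for ", gene, ": fewer than 3 shared ",
                "samples")
        selection$rnaseq_rho <- NA_real_
        selection$validated <- NA
        return(selection)
    }
    ref <- exprValues(rnaseq)[gene, shared]
    rho <- vapply(probes, function(p)
        spearmanRho(exprValues(expr)[p, shared], ref), numeric(1))
    best <- probes[order(-rho, probes)[1]]
    selection$rnaseq_rho <- unname(rho[selection$selected_probe])
    selection$validated <- identical(best, selection$selected_probe)
    if (!selection$validated)
        warning("intensity-selected probe ", selection$selected_probe,
                " for ", gene, " does not maximize RNA-seq correlation (",
                best, " does); keeping the intensity choice")
    attr(selection, "all_rho") <- rho
    selection
}

#' Collapse a probe-level matrix to genes using a selection table
#'
#' @param expr \linkS4class{BrainExpression}, probes x samples.
#' @param selection data.frame from \code{\link{selectProbes}}.
#' @return \linkS4class{BrainExpression} with one row per gene (gene
#'   symbols as rownames), same samples and valueKind.
#' @export
collapseToGenes <- function(expr, selection) {
    m <- exprValues(expr)[selection$selected_probe, , drop = FALSE]
    rownames(m) <- selection$gene_symbol
    BrainExpression(m, valueKind = valueKind(expr),
                    sampleInfo = sampleInfo(expr))
}
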