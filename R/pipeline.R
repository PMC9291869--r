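## End-to-end orchestration over one or more statistic maps, driven by a
## structured config. Every ambiguous analysis choice (map polarity,
## classification mode, pair filter rule, Bonferroni family sizes) is
## recorded in the run manifest even when defaulted.

.default_config <- function() {
    list(alpha = 0.05, mode = "interpolate_then_threshold",
         membership_cutoff = 0, male_only = FALSE,
         female_donors = character(0), genes = .DEFAULT_GENES,
         focus_gene = "OXTR", filter_rule = "either",
         gate_on_steiger = FALSE, coexpr_map = NULL,
         rnaseq_donors = c("donor1", "donor2"), seed = 1L)
}

#' Read a pipeline run configuration
#'
#' @param path YAML file whose fields mirror the arguments of
#'   \code{\link{runPipeline}}: input paths (\code{samples},
#'   \code{expression}, \code{probe_map}, optional \code{rnaseq}), a
#'   \code{maps} list of \code{name}/\code{path}/\code{semantics}
#'   entries, and the analysis options (\code{alpha}, \code{mode},
#'   \code{membership_cutoff}, \code{male_only}, \code{female_donors},
#'   \code{genes}, \code{focus_gene}, \code{filter_rule},
#'   \code{gate_on_steiger}, \code{coexpr_map}, \code{out_dir}).
#' @return config list with defaults filled in.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- yaml::read_yaml(path)
    defaults <- .default_config()
    for (nm in names(defaults))
        if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
    cfg$genes <- as.character(cfg$genes)
    if (is.null(cfg$maps) || !length(cfg$maps))
        stop("config must list at least one statistic map")
    if (!length(cfg$genes)) stop("config must list genes of interest")
    cfg
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full imaging-transcriptomics pipeline
#'
#' Executes load, probe selection (with RNA-seq validation when an
#' RNA-seq matrix is supplied), optional male-only donor drop, donor
#' batch correction, z-normalization, per-map sample classification,
#' per-map per-compartment differential expression, and the differential
#' co-expression contrast on the designated map. Batch correction and
#' normalization are computed on each map's retained (non-excluded)
#' samples. All result tables plus a JSON manifest are written to
#' \code{out_dir} when set; on any stage error, a directory created by
#' this run is removed.
#'
#' @param config a config list (see \code{\link{readRunConfig}}) or a
#'   path to a YAML config file.
#' @return invisibly, the result bundle: \code{classification} (per map),
#'   \code{counts} (per map), \code{differential}, \code{pairs},
#'   \code{coexpression} (\linkS4class{CorrelationComparison} per
#'   compartment), \code{selection}, \code{manifest}.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- readRunConfig(config)
    defaults <- .default_config()
    for (nm in names(defaults))
        if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]

    outDir <- config$out_dir
    createdDir <- !is.null(outDir) && !dir.exists(outDir)
    run <- function() {
        samples <- .stage("load-samples", readSamples(config$samples))
        expr <- .stage("load-expression",
                       readExpression(config$expression))
        expr <- BrainExpression(exprValues(expr), valueKind(expr),
                                sampleInfo = samples)
        probeMap <- .stage("load-probe-map", readProbeMap(config$probe_map))
        vols <- .stage("load-maps", lapply(config$maps, function(mp)
            readStatVolume(mp$path,
                           if (is.null(mp$semantics)) "p_value"
                           else mp$semantics)))
        names(vols) <- vapply(config$maps, `[[`, "", "name")

        selection <- .stage("probe-selection",
                            selectProbes(expr, probeMap, config$genes))
        if (!is.null(config[["rnaseq"]])) {
            rnaseq <- .stage("load-rnaseq",
                             readExpression(config[["rnaseq"]], "rnaseq"))
            selection <- .stage("probe-validation", do.call(rbind,
                lapply(seq_len(nrow(selection)), function(i)
                    validateSelection(selection[i, , drop = FALSE], expr,
                                      rnaseq, probeMap,
                                      config$rnaseq_donors))))
        }
        geneExpr <- .stage("collapse", collapseToGenes(expr, selection))
        if (isTRUE(config$male_only))
            geneExpr <- .stage("male-only-drop",
                dropDonorColumns(geneExpr, config$female_donors))

        classification <- list(); counts <- list()
        differential <- list()
        exprZByMap <- list()
        for (nm in names(vols)) {
            cls <- .stage(paste0("classify-", nm),
                classifySamples(samples, vols[[nm]], mode = config$mode,
                                alpha = config$alpha,
                                membershipCutoff =
                                    config$membership_cutoff))
            classification[[nm]] <- cls
            counts[[nm]] <- countByGroup(cls)
            keep <- cls$sample_id[!cls$excluded]
            keep <- intersect(colnames(geneExpr), keep)
            retained <- BrainExpression(
                exprValues(geneExpr)[, keep, drop = FALSE],
                valueKind(geneExpr),
                sampleInfo = sampleInfo(geneExpr)[keep, , drop = FALSE])
            z <- .stage(paste0("normalize-", nm),
                        zNormalize(removeDonorEffects(retained)))
            exprZByMap[[nm]] <- z
            differential[[nm]] <- .stage(paste0("diffexpr-", nm),
                differentialExpression(z, cls, config$genes,
                                       mapName = nm))
        }
        coMap <- if (is.null(config$coexpr_map)) names(vols)[1]
                 else config$coexpr_map
        coex <- list(); pairTabs <- list()
        for (comp in c("subcortex", "cortex")) {
            cc <- .stage(paste0("coexpression-", comp),
                coexpressionContrast(exprZByMap[[coMap]],
                                     classification[[coMap]],
                                     config$genes,
                                     focusGene = config$focus_gene,
                                     compartment = comp,
                                     filterRule = config$filter_rule,
                                     gateOnSteiger =
                                         config$gate_on_steiger,
                                     mapName = coMap))
            coex[[comp]] <- cc
            pairTabs[[comp]] <- cc@fisher
        }
        differential <- do.call(rbind, c(differential,
                                         make.row.names = FALSE))
        pairs <- do.call(rbind, c(pairTabs, make.row.names = FALSE))

        manifest <- list(
            config = list(
                alpha = config$alpha, mode = config$mode,
                membership_cutoff = config$membership_cutoff,
                male_only = isTRUE(config$male_only),
                female_donors = config$female_donors,
                genes = config$genes, focus_gene = config$focus_gene,
                filter_rule = config$filter_rule,
                gate_on_steiger = isTRUE(config$gate_on_steiger),
                coexpr_map = coMap, seed = config$seed,
                maps = lapply(config$maps, function(mp)
                    list(name = mp$name, semantics =
                         if (is.null(mp$semantics)) "p_value"
                         else mp$semantics))),
            value_kind_chain = c("log2_intensity", "batch_corrected",
                                 "z_scored"),
            bonferroni_family_differential = length(config$genes),
            counts = lapply(counts, function(tb)
                as.list(setNames(as.vector(tb),
                                 paste(rep(rownames(tb), 2),
                                       rep(colnames(tb), each = 2),
                                       sep = "_")))),
            probe_selection = selection[,
                intersect(c("gene_symbol", "selected_probe",
                            "mean_intensity", "rnaseq_rho", "validated"),
                          names(selection))],
            coexpression = lapply(coex, function(cc) list(
                steiger_chi2 = cc@steiger$chi2,
                steiger_df = cc@steiger$df, steiger_p = cc@steiger$p,
                n_affected = cc@n1, n_unaffected = cc@n2,
                retained_pairs = nrow(cc@fisher),
                filter_rule = cc@filterRule)))

        bundle <- list(classification = classification, counts = counts,
                       differential = differential, pairs = pairs,
                       coexpression = coex, selection = selection,
                       manifest = manifest)
        if (!is.null(outDir))
            .stage("write-results", writeResults(
                list(differential = differential, pairs = pairs,
                     classification = classification,
                     summary = manifest), outDir))
        bundle
    }
    tryCatch(run(), error = function(e) {
        if (createdDir && dir.exists(outDir))
            unlink(outDir, recursive = TRUE)
        stop(e)
    })
}

#' Summarize a result bundle as a plain-text report
#'
#' @param bundle result of \code{\link{runPipeline}}, or a directory
#'   written by it (the TSV/JSON outputs are then re-read).
#' @return character vector of report lines (invisibly); the report is
#'   printed.
#' @export
summarizeRun <- function(bundle) {
    if (is.character(bundle)) {
        dir <- bundle
        de <- read.delim(file.path(dir, "differential_expression.tsv"),
                         stringsAsFactors = FALSE)
        pr <- read.delim(file.path(dir, "coexpression_pairs.tsv"),
                         stringsAsFactors = FALSE)
        sm <- jsonlite::read_json(file.path(dir, "summary.json"))
        bundle <- list(differential = de, pairs = pr, manifest = sm)
    }
    de <- bundle$differential
    lines <- c("Differential expression (affected vs unaffected)",
               "================================================")
    if (is.null(de) || !nrow(de) || all(de$untestable)) {
        lines <- c(lines, "no tests performed")
    } else {
        for (mp in unique(de$map_name)) {
            lines <- c(lines, paste0("map: ", mp))
            sub <- de[de$map_name == mp & !de$untestable, , drop = FALSE]
            if (!nrow(sub)) {
                lines <- c(lines, "  no tests performed")
                next
            }
            for (i in seq_len(nrow(sub))) {
                star <- if (isTRUE(sub$significant[i] > 0)) " *" else ""
                lines <- c(lines, sprintf(
                    "  %-10s %-9s dz=%+.3f  p_bonf=%.3g%s",
                    sub$compartment[i], sub$gene[i], sub$mean_diff_z[i],
                    sub$p_bonf[i], star))
            }
        }
    }
    lines <- c(lines, "", "Differential co-expression",
               "==========================")
    co <- bundle$manifest$coexpression
    for (comp in names(co)) {
        cc <- co[[comp]]
        lines <- c(lines, sprintf(
            "%s: Steiger chi2 = %.4g, df = %d, p = %.3g (n = %d/%d)",
            comp, as.numeric(cc$steiger_chi2),
            as.integer(cc$steiger_df), as.numeric(cc$steiger_p),
            as.integer(cc$n_affected), as.integer(cc$n_unaffected)))
    }
    pr <- bundle$pairs
    if (!is.null(pr) && nrow(pr)) {
        for (i in seq_len(nrow(pr))) {
            star <- if (isTRUE(pr$significant[i] > 0)) " *" else ""
            lines <- c(lines, sprintf(
                "  %s %s-%s r=%.3f vs %.3f  z=%.3f  p_bonf=%.3g%s",
                pr$compartment[i], pr$gene_a[i], pr$gene_b[i],
                pr$r_affected[i], pr$r_unaffected[i], pr$z_stat[i],
                pr$p_bonf[i], star))
        }
    } else {
        lines <- c(lines, "  no retained pairs")
    }
    cat(lines, sep = "\n")
    invisible(lines)
}
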