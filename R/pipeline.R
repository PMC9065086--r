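#' Configuration for a replicate-generation run
#'
#' Bundles and validates everything [run_pipeline()] needs: the strategy, the
#' number of artificial replicates, strategy-specific tuning, selection
#' thresholds, seeds and input/output locations.
#'
#' @param strategy `"FB"` (FASTQ read bootstrap), `"CB"` (column bootstrap)
#'   or `"MO"` (mixing observations).
#' @param out_dir Run directory; created if missing.
#' @param B Number of artificial replicates (default 10).
#' @param counts Reference [count_matrix()]; required for CB and MO, and used
#'   as the reference analysis for FB when given (otherwise quantified from
#'   `fastq`).
#' @param fastq Named list (one entry per sample) of FASTQ paths; required
#'   for FB.
#' @param transcriptome FASTA path or named sequences for the FB quantifier.
#' @param quantifier Function `(fastq_path, transcriptome) ->` object with a
#'   `counts` vector; default [quantify_exact()]. Swap in a wrapper around a
#'   real aligner-based counter for non-toy data.
#' @param groups Group label per sample (required with `fastq` when `counts`
#'   is absent).
#' @param pi FB read fraction in (0, 1].
#' @param stratify CB: resample within condition groups.
#' @param dirichlet_alpha,weights,within_group MO mixing controls, see
#'   [mix_observations()].
#' @param alpha,lfc_threshold Gene-selection thresholds (defaults 0.05 and 2).
#' @param seed Base seed; replicate `b` uses seed `seed + b`.
#' @param gmt Optional GMT path; when given, over-representation analysis is
#'   run for the reference and every replicate.
#' @param de_backend `"builtin"` for [nb_wald()] or a function
#'   `(count_matrix) -> nb_de` for an external engine.
#' @param reclaim_space FB: delete each bootstrapped FASTQ once its counts
#'   are produced.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(strategy = c("CB", "MO", "FB"), out_dir,
                            B = 10, counts = NULL, fastq = NULL,
                            transcriptome = NULL, quantifier = quantify_exact,
                            groups = NULL, pi = 1, stratify = TRUE,
                            dirichlet_alpha = 1, weights = NULL,
                            within_group = TRUE, alpha = 0.05,
                            lfc_threshold = 2, seed = 1, gmt = NULL,
                            de_backend = "builtin", reclaim_space = FALSE) {
  strategy <- match.arg(strategy)
  if (B < 1L) stopf("'B' must be at least 1")
  if (strategy == "FB") {
    if (is.null(fastq) || !length(fastq))
      stopf("FB needs 'fastq': one FASTQ path per sample")
    if (is.null(names(fastq)) || anyDuplicated(names(fastq)))
      stopf("'fastq' must be a named list with unique sample ids")
    if (is.null(transcriptome)) stopf("FB needs a 'transcriptome' for quantification")
    if (is.null(counts) && is.null(groups))
      stopf("FB needs 'groups' (or a reference 'counts') to label samples")
    if (pi <= 0 || pi > 1) stopf("'pi' must be in (0, 1]")
  } else {
    if (is.null(counts)) stopf("%s needs a reference 'counts' matrix", strategy)
  }
  if (!is.null(counts)) stopifnot(inherits(counts, "count_matrix"))
  if (!identical(de_backend, "builtin") && !is.function(de_backend))
    stopf("'de_backend' must be \"builtin\" or a function")
  structure(list(strategy = strategy, out_dir = out_dir, B = as.integer(B),
                 counts = counts, fastq = fastq, transcriptome = transcriptome,
                 quantifier = quantifier, groups = groups, pi = pi,
                 stratify = stratify, dirichlet_alpha = dirichlet_alpha,
                 weights = weights, within_group = within_group,
                 alpha = alpha, lfc_threshold = lfc_threshold,
                 seed = as.integer(seed), gmt = gmt, de_backend = de_backend,
                 reclaim_space = reclaim_space),
            class = "pipeline_config")
}

#' Run the full replicate-generation and evaluation workflow
#'
#' Generate `B` artificial replicates with the configured strategy, run
#' differential expression (and optionally over-representation analysis) on
#' the reference data and on every replicate, and write the comparison
#' artifacts: Spearman-distance matrix and Ward tree (Newick), asymmetric
#' overlap matrix of the gene selections, the selection-frequency stability
#' cross-tabulation, and a JSON manifest with every seed and output file
#' hash. Reruns with the same configuration and builtin DE backend are
#' bit-identical. Any stage error aborts the run with the stage name;
#' partial runs are not resumed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of class `pipeline_run` with the reference
#'   result, per-replicate results and selections, evaluation objects and
#'   the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  rep_dir <- file.path(config$out_dir, "replicates")
  de_dir <- file.path(config$out_dir, "de")
  ev_dir <- file.path(config$out_dir, "evaluation")
  for (p in c(rep_dir, de_dir, ev_dir))
    dir.create(p, showWarnings = FALSE)

  run_de <- function(x) {
    if (identical(config$de_backend, "builtin")) nb_wald(x)
    else config$de_backend(x)
  }
  gene_sets <- if (!is.null(config$gmt)) read_gmt(config$gmt)

  reference <- stage("reference", {
    if (!is.null(config$counts)) config$counts
    else {
      quant <- lapply(names(config$fastq), function(s)
        config$quantifier(config$fastq[[s]], config$transcriptome)$counts)
      m <- do.call(cbind, quant)
      colnames(m) <- names(config$fastq)
      count_matrix(m, config$groups)
    }
  })
  ref_de <- stage("reference_de", run_de(reference))
  ref_sel <- select_genes(ref_de, config$alpha, config$lfc_threshold)
  write_counts_tsv(reference, file.path(config$out_dir, "reference_counts.tsv"),
                   file.path(config$out_dir, "reference_groups.tsv"))
  write_de_tsv(ref_de, file.path(de_dir, "reference_de.tsv"))

  universe <- ref_de$gene_id[!is.na(ref_de$pvalue)]
  ref_ora <- if (!is.null(gene_sets))
    stage("reference_ora", {
      r <- fisher_ora(intersect(ref_sel, universe), universe, gene_sets,
                      config$alpha)
      write_ora_tsv(r, file.path(de_dir, "reference_ora.tsv"))
      r
    })

  matrices <- vector("list", config$B)
  de_results <- vector("list", config$B)
  selections <- vector("list", config$B)
  ora_results <- vector("list", config$B)
  for (b in seq_len(config$B)) {
    seed_b <- config$seed + b
    lab <- sprintf("%s%d", config$strategy, b)
    mat <- stage(paste0("generate_", lab), switch(
      config$strategy,
      CB = column_bootstrap(reference, stratify = config$stratify,
                            seed = seed_b),
      MO = mix_observations(reference, weights = config$weights,
                            dirichlet_alpha = config$dirichlet_alpha,
                            within_group = config$within_group, seed = seed_b),
      FB = {
        samples <- names(config$fastq)
        quant <- lapply(seq_along(samples), function(i) {
          out <- file.path(rep_dir, sprintf("%s_%s.fastq", lab, samples[i]))
          bootstrap_fastq(config$fastq[[samples[i]]], out, pi = config$pi,
                          seed = derive_seed(seed_b, i))
          cnt <- config$quantifier(out, config$transcriptome)$counts
          if (config$reclaim_space) unlink(out)
          cnt
        })
        m <- do.call(cbind, quant)
        colnames(m) <- paste0(samples, ".", lab)
        count_matrix(m, as.character(reference$groups))
      }))
    if (config$strategy != "FB" || !config$reclaim_space)
      write_counts_tsv(mat, file.path(rep_dir, paste0(lab, "_counts.tsv")),
                       file.path(rep_dir, paste0(lab, "_groups.tsv")))
    der <- stage(paste0("de_", lab), run_de(mat))
    write_de_tsv(der, file.path(de_dir, paste0(lab, "_de.tsv")))
    matrices[[b]] <- mat
    de_results[[b]] <- der
    selections[[b]] <- select_genes(der, config$alpha, config$lfc_threshold)
    if (!is.null(gene_sets)) {
      uni_b <- der$gene_id[!is.na(der$pvalue)]
      ora_results[[b]] <- stage(paste0("ora_", lab), {
        r <- fisher_ora(intersect(selections[[b]], uni_b), uni_b, gene_sets,
                        config$alpha)
        write_ora_tsv(r, file.path(de_dir, paste0(lab, "_ora.tsv")))
        r
      })
    }
  }
  labels <- sprintf("%s%d", config$strategy, seq_len(config$B))
  names(matrices) <- names(de_results) <- names(selections) <- labels

  evaluation <- stage("evaluation", {
    all_de <- c(list(reference = ref_de), de_results)
    dmat <- spearman_distance(de_catalog(all_de, "pvalue"))
    write_matrix_tsv(dmat, file.path(ev_dir, "spearman_distance_pvalue.tsv"),
                     digits = 6)
    tree <- ward_tree(dmat)
    tree_newick(tree, file.path(ev_dir, "pvalue_tree.nwk"))
    ovl <- overlap_matrix(c(list(reference = ref_sel), selections))
    write_matrix_tsv(ovl, file.path(ev_dir, "overlap_selected_genes.tsv"))
    stab <- stability_report(ref_sel, selections, ref_de$gene_id,
                             setNames(ref_de$pvalue, ref_de$gene_id))
    write_stability_tsv(stab, file.path(ev_dir, "stability_crosstab.tsv"))
    disp <- dispersion_comparison(c(list(reference = reference), matrices),
                                  mode = "biological", reference = "reference")
    utils::write.table(
      data.frame(dataset = names(disp$ks), ks_to_reference = round(disp$ks, 6)),
      file.path(ev_dir, "dispersion_ks.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    list(distance = dmat, tree = tree, overlap = ovl, stability = stab,
         dispersion = disp)
  })

  manifest <- stage("manifest", {
    files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
    files <- setdiff(files, file.path(config$out_dir, "manifest.json"))
    man <- list(
      strategy = config$strategy, B = config$B, seed = config$seed,
      replicate_seeds = config$seed + seq_len(config$B),
      pi = if (config$strategy == "FB") config$pi,
      dirichlet_alpha = if (config$strategy == "MO") config$dirichlet_alpha,
      stratify = if (config$strategy == "CB") config$stratify,
      alpha = config$alpha, lfc_threshold = config$lfc_threshold,
      package_version = as.character(utils::packageVersion("bootreps")),
      files = as.list(tools::md5sum(files)))
    jsonlite::write_json(man, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    man
  })

  invisible(structure(list(
    config = config, reference = reference, reference_de = ref_de,
    reference_selection = ref_sel, reference_ora = ref_ora,
    matrices = matrices, de = de_results, selections = selections,
    ora = ora_results, evaluation = evaluation, manifest = manifest),
    class = "pipeline_run"))
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("pipeline_run: strategy %s, B = %d, out_dir = %s\n",
              x$config$strategy, x$config$B, x$config$out_dir))
  cat(sprintf("  reference selection: %d genes; replicate selections: %s\n",
              length(x$reference_selection),
              paste(lengths(x$selections), collapse = ", ")))
  invisible(x)
}
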