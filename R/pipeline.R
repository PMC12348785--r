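# Pipeline driver: simulate (or load) -> methylation levels -> DMRs ->
# sRNA clusters/DSRs -> DEGs -> integration -> RdDM screen, with every
# intermediate written as TSV and a JSON run manifest. Re-running with the
# same config and seed reproduces byte-identical result tables.

#' Pipeline run configuration
#'
#' @param sim A [sim_config()] to generate inputs, or `NULL` to load them
#'   from `input_dir`.
#' @param input_dir Directory holding `genome.fa`, `genes.gff3`, `te.bed`,
#'   `samples.tsv`, `cx/*.CX_report.txt`, `srna.tsv`, `gene_counts.tsv`
#'   (the layout written by [write_simulation()]); ignored when `sim` is
#'   given.
#' @param dmr A [dmr_params()].
#' @param spec A [region_spec()].
#' @param contexts Cytosine contexts to analyse.
#' @param comparisons List of `c(treat_dpt, ctrl_dpt)` pairs.
#' @param screen_comparison The comparison used for the RdDM screen.
#' @param screen_mode `"canonical"` or `"mirror"`.
#' @param alpha,min_abs_log2fc DSR/DEG thresholds.
#' @param write_inputs Also write the simulated inputs under
#'   `<out_dir>/inputs` (off by default; the truth tables are always
#'   written when simulating).
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(), input_dir = NULL,
                       dmr = dmr_params(), spec = region_spec(),
                       contexts = c("CG", "CHG", "CHH"),
                       comparisons = list(c(5, 0), c(10, 0)),
                       screen_comparison = c(10, 0),
                       screen_mode = "canonical",
                       alpha = 0.05, min_abs_log2fc = 1,
                       write_inputs = FALSE) {
  if (is.null(sim) && is.null(input_dir)) {
    abort("either a simulation config or an input directory is required")
  }
  structure(list(sim = sim, input_dir = input_dir, dmr = dmr, spec = spec,
                 contexts = contexts, comparisons = comparisons,
                 screen_comparison = screen_comparison,
                 screen_mode = screen_mode, alpha = alpha,
                 min_abs_log2fc = min_abs_log2fc,
                 write_inputs = write_inputs),
            class = "run_config")
}

cmp_label <- function(pair) sprintf("%gdpt_vs_%gdpt", pair[1], pair[2])

load_run_inputs <- function(input_dir) {
  genome <- read_genome_fasta(file.path(input_dir, "genome.fa"))
  samples <- read_sample_sheet(file.path(input_dir, "samples.tsv"))
  meth_ids <- filter(samples, .data$assay == "wgbs")$sample_id
  meth <- purrr::map(meth_ids, function(sid) {
    read_cx_report(file.path(input_dir, "cx",
                             paste0(sid, ".CX_report.txt")),
                   sample_id = sid)
  }) %>% bind_rows()
  truth_dir <- file.path(input_dir, "truth")
  list(genome = genome, chrom_lengths = chrom_lengths(genome),
       genes = read_gene_models(file.path(input_dir, "genes.gff3")),
       te = read_te_bed(file.path(input_dir, "te.bed")),
       samples = samples, meth = meth,
       srna = read_srna_table(file.path(input_dir, "srna.tsv")),
       expr = read_count_matrix(file.path(input_dir, "gene_counts.tsv")),
       truth = if (dir.exists(truth_dir)) read_truth(truth_dir) else NULL)
}

#' Run the full integrative pipeline
#'
#' Executes simulate/load, methylation levels, DMR calling, sRNA
#' clustering + DSR calling, DEG calling, DMR-DSR association, DMR target
#' genes + DEG intersection, and the RdDM candidate screen, writing every
#' result table as TSV under `out_dir` plus a JSON manifest with
#' parameters, row counts and file checksums. A stage failure aborts with
#' the stage name.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with all result tables, the inputs and the
#'   manifest.
#' @export
run_rddm_pipeline <- function(config = run_config(), out_dir,
                              quiet = FALSE) {
  t0 <- Sys.time()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(stage, ...) {
    if (!quiet) message(sprintf("[rddmscan:%s] %s", stage,
                                paste0(..., collapse = "")))
  }
  stage <- function(name, expr) {
    say(name, "start")
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(as_tibble(df), path, progress = FALSE)
    outputs <<- c(outputs, name)
    df
  }

  inp <- stage("inputs", {
    if (!is.null(config$sim)) {
      sim <- simulate_dataset(config$sim)
      if (isTRUE(config$write_inputs)) {
        write_simulation(sim, file.path(out_dir, "inputs"))
      } else if (!is.null(sim$truth)) {
        write_truth(sim$truth, file.path(out_dir, "truth"))
      }
      sim
    } else {
      load_run_inputs(config$input_dir)
    }
  })

  levels_tbl <- stage("levels", {
    emit(global_level(inp$meth), "global_levels.tsv")
  })

  dmrs <- stage("dmr", {
    res <- purrr::map(config$comparisons, function(pair) {
      treat <- samples_at(inp$samples, "wgbs", pair[1])
      ctrl <- samples_at(inp$samples, "wgbs", pair[2])
      purrr::map(config$contexts, function(ctx) {
        call_dmrs(inp$meth, treat, ctrl, context = ctx,
                  params = config$dmr,
                  chrom_lengths = inp$chrom_lengths,
                  comparison = cmp_label(pair))
      }) %>% setNames(config$contexts)
    }) %>% setNames(purrr::map_chr(config$comparisons, cmp_label))
    all_tbl <- bind_rows(purrr::map(res, bind_rows))
    emit(all_tbl, "dmr_all.tsv")
    for (cmp in names(res)) {
      emit(dmr_distribution(bind_rows(res[[cmp]]), inp$genes, inp$te,
                            config$spec),
           sprintf("dmr_distribution_%s.tsv", cmp))
    }
    res
  })

  srna_res <- stage("dsr", {
    clusters <- bin_srna_reads(inp$srna, bin_width = config$dmr$tile_width)
    emit(srna_length_distribution(inp$srna), "srna_length_distribution.tsv")
    dsrs <- purrr::map(config$comparisons, function(pair) {
      treat <- samples_at(inp$samples, "srna", pair[1])
      ctrl <- samples_at(inp$samples, "srna", pair[2])
      d <- call_dsrs(clusters, treat, ctrl, alpha = config$alpha,
                     min_abs_log2fc = config$min_abs_log2fc,
                     comparison = cmp_label(pair))
      emit(d, sprintf("dsr_%s.tsv", cmp_label(pair)))
      emit(dsr_summary(d), sprintf("dsr_summary_%s.tsv", cmp_label(pair)))
      d
    }) %>% setNames(purrr::map_chr(config$comparisons, cmp_label))
    list(clusters = clusters, dsrs = dsrs)
  })

  degs <- stage("deg", {
    purrr::map(config$comparisons, function(pair) {
      treat <- samples_at(inp$samples, "rna", pair[1])
      ctrl <- samples_at(inp$samples, "rna", pair[2])
      d <- call_degs(inp$expr, treat, ctrl, alpha = config$alpha,
                     min_abs_log2fc = config$min_abs_log2fc,
                     comparison = cmp_label(pair))
      emit(d, sprintf("deg_%s.tsv", cmp_label(pair)))
      d
    }) %>% setNames(purrr::map_chr(config$comparisons, cmp_label))
  })

  assoc <- stage("integrate", {
    rows <- purrr::map(names(dmrs), function(cmp) {
      purrr::map(config$contexts, function(ctx) {
        d24 <- filter(as_tibble(srna_res$dsrs[[cmp]]),
                      .data$size_class == "24nt")
        attr(d24, "comparison") <- cmp
        associate_all(d24, srna_res$clusters, dmrs[[cmp]][[ctx]]) %>%
          mutate(context = ctx, comparison = cmp, .before = 1)
      }) %>% bind_rows()
    }) %>% bind_rows()
    emit(rows, "dmr_dsr_association.tsv")
    venns <- purrr::map(names(dmrs), function(cmp) {
      purrr::map(config$contexts, function(ctx) {
        tg <- dmr_target_genes(dmrs[[cmp]][[ctx]], inp$genes, config$spec,
                               degs = degs[[cmp]],
                               chrom_lengths = inp$chrom_lengths)
        emit(tg, sprintf("dmr_targets_%s_%s.tsv", ctx, cmp))
        deg_tbl <- as_tibble(degs[[cmp]])
        venn_counts(tg$gene_id,
                    deg_tbl$feature_id[deg_tbl$direction == "up"],
                    deg_tbl$feature_id[deg_tbl$direction == "down"]) %>%
          mutate(context = ctx, comparison = cmp, .before = 1)
      }) %>% bind_rows()
    }) %>% bind_rows()
    emit(venns, "dmr_target_venn.tsv")
    rows
  })

  screen <- stage("screen", {
    cmp <- cmp_label(config$screen_comparison)
    if (!cmp %in% names(dmrs)) {
      abort(paste0("screen comparison ", cmp, " was not analysed"))
    }
    d24 <- filter(as_tibble(srna_res$dsrs[[cmp]]),
                  .data$size_class == "24nt")
    attr(d24, "comparison") <- cmp
    sc <- screen_rddm(dmrs[[cmp]][["CHH"]], srna_res$clusters, d24,
                      degs[[cmp]], inp$genes, inp$te, config$spec,
                      mode = config$screen_mode,
                      chrom_lengths = inp$chrom_lengths)
    emit(sc, "rddm_candidates.tsv")
    sc
  })

  manifest <- stage("manifest", {
    tables <- purrr::map(outputs, function(nm) {
      path <- file.path(out_dir, nm)
      n <- length(readr::read_lines(path, progress = FALSE)) - 1L
      list(file = nm, rows = n,
           md5 = unname(tools::md5sum(path)))
    })
    m <- list(
      package = "rddmscan",
      version = as.character(packageVersion("rddmscan")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = if (!is.null(config$sim)) config$sim$seed else NA,
      parameters = list(
        dmr = unclass(config$dmr), spec = unclass(config$spec),
        alpha = config$alpha, min_abs_log2fc = config$min_abs_log2fc,
        contexts = config$contexts,
        comparisons = purrr::map_chr(config$comparisons, cmp_label),
        screen_comparison = cmp_label(config$screen_comparison),
        screen_mode = config$screen_mode,
        sim = if (!is.null(config$sim)) unclass(config$sim) else NULL),
      stages = c("inputs", "levels", "dmr", "dsr", "deg", "integrate",
                 "screen"),
      tables = tables,
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
    jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    m
  })

  # self-consistency: manifest row counts match the written tables
  for (tb in manifest$tables) {
    n <- length(readr::read_lines(file.path(out_dir, tb$file),
                                  progress = FALSE)) - 1L
    if (n != tb$rows) {
      abort(sprintf("manifest row count mismatch for %s", tb$file))
    }
  }
  say("done", sprintf("%d tables in %s", length(outputs), out_dir))
  invisible(list(inputs = inp, levels = levels_tbl, dmrs = dmrs,
                 clusters = srna_res$clusters, dsrs = srna_res$dsrs,
                 degs = degs, association = assoc, screen = screen,
                 manifest = manifest))
}
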