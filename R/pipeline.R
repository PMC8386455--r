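#' Run the proteorhodopsin quantification pipeline
#'
#' Orchestrates screen -> annotate -> cluster -> abundance -> transcription ->
#' qPCR from one configuration, persisting each stage's outputs as TSV under
#' the output directory together with a stage-status manifest. A stage whose
#' inputs are absent from the configuration is skipped; a failing stage halts
#' the run (its error names the stage) and downstream stages are marked
#' \code{not_run}. Re-running with unchanged inputs produces byte-identical
#' outputs.
#'
#' Configuration fields (paths unless noted): \code{proteins} (FASTA of
#' candidate proteins), \code{panel} (FASTA reference panel for the internal
#' search), \code{hits} (external hit table; takes precedence over the
#' internal search), \code{reference} (annotated reference FASTA; default the
#' bundled one), \code{dna_counts}, \code{rna_counts}, \code{qpcr_standards},
#' \code{qpcr_samples}, \code{outdir}, and scalars \code{min_length_aa}
#' (default 100), \code{identity_threshold} (default 0.82).
#'
#' @param config a named list or the path to a YAML file with the fields above.
#' @return object of class \code{"pipeline_run"}: list with \code{manifest}
#'   (data.frame stage/status/output), \code{results} (per-stage objects),
#'   \code{outdir}, \code{warnings}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  outdir <- config$outdir
  if (is.null(outdir)) stop("config must set 'outdir'")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (f in c("proteins", "panel", "hits", "dna_counts", "rna_counts",
              "qpcr_standards", "qpcr_samples", "reference"))
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop("config error: ", f, " file not found: ", config[[f]])

  stages <- c("screen", "annotate", "cluster", "abundance", "transcription", "qpcr")
  status <- stats::setNames(rep("not_run", length(stages)), stages)
  outputs <- stats::setNames(rep("", length(stages)), stages)
  results <- list(); warns <- character(0)

  cfg <- screen_config(min_length_aa = config$min_length_aa %||% 100L)
  ref <- if (!is.null(config$reference))
    annotated_reference(read_proteins(config$reference)[[1L]]) else pr_reference()

  out <- function(f) file.path(outdir, f)
  wtab <- function(df, f) {
    utils::write.table(df, out(f), sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    f
  }
  run_stage <- function(stage, fun) {
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e) {
        status[stage] <<- "failed"
        manifest <- data.frame(stage = stages, status = unname(status),
                               output = unname(outputs), stringsAsFactors = FALSE)
        utils::write.table(manifest, out("manifest.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }),
      warning = function(w) {
        warns <<- c(warns, paste0(stage, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    status[stage] <<- "ok"
    res
  }

  curated_records <- NULL

  ## screen
  if (!is.null(config$proteins)) {
    results$screen <- run_stage("screen", function() {
      records <- read_proteins(config$proteins)
      hits <- if (!is.null(config$hits)) {
        import_external_hits(config$hits, cfg)
      } else if (!is.null(config$panel)) {
        search_candidates(records, read_proteins(config$panel), cfg)
      } else NULL
      candidates <- if (!is.null(hits)) records[hits$query_id] else records
      screened <- curate_candidates(candidates, ref, cfg)
      outputs["screen"] <<- wtab(screened, "screen_results.tsv")
      curated_records <<- candidates[screened$query_id[screened$retained]]
      write_proteins(curated_records, out("curated.faa"))
      list(results = screened, hits = hits)
    })
  } else status["screen"] <- "skipped"

  ## annotate
  if (!is.null(curated_records) && length(curated_records)) {
    results$annotate <- run_stage("annotate", function() {
      ann <- annotate_proteins(curated_records, ref)
      outputs["annotate"] <<- wtab(ann, "annotations.tsv")
      prof <- do.call(rbind, lapply(c(97, 101, 105, 108), function(p) {
        pr <- position_profile(ann, p)
        data.frame(position = p, residue = names(pr$counts),
                   count = pr$counts, frequency = pr$frequencies,
                   gap_count = pr$gap_count, row.names = NULL,
                   stringsAsFactors = FALSE)
      }))
      wtab(prof, "position_profiles.tsv")
      ann
    })
  } else status["annotate"] <- "skipped"

  ## cluster
  if (!is.null(curated_records) && length(curated_records)) {
    results$cluster <- run_stage("cluster", function() {
      cl <- cluster_greedy(curated_records,
                           identity_threshold = config$identity_threshold %||% 0.82)
      outputs["cluster"] <<- "clusters.tsv"
      write_clusters(cl, out("clusters.tsv"))
      cl
    })
  } else status["cluster"] <- "skipped"

  ## abundance
  if (!is.null(config$dna_counts)) {
    results$abundance <- run_stage("abundance", function() {
      tab <- read_gene_counts(config$dna_counts)
      res <- lapply(unique(tab$sample_id), function(s) {
        fr <- pr_bearing_fraction(tab, s)
        sh <- otu_relative_abundance(tab, s)
        list(fraction = fr, otu_shares = sh)
      })
      names(res) <- unique(tab$sample_id)
      fr_df <- do.call(rbind, lapply(res, function(r)
        data.frame(sample_id = r$fraction$sample_id,
                   t(r$fraction$per_housekeeping_ratio),
                   pr_fraction = r$fraction$pr_fraction,
                   flag_gt1 = r$fraction$flag_gt1, check.names = FALSE)))
      outputs["abundance"] <<- wtab(fr_df, "abundance.tsv")
      sh_df <- do.call(rbind, lapply(names(res), function(s)
        data.frame(sample_id = s, otu_id = names(res[[s]]$otu_shares),
                   share = unname(res[[s]]$otu_shares))))
      wtab(sh_df, "otu_shares.tsv")
      res
    })
  } else status["abundance"] <- "skipped"

  ## transcription
  if (!is.null(config$rna_counts)) {
    results$transcription <- run_stage("transcription", function() {
      tab <- read_gene_counts(config$rna_counts)
      res <- lapply(unique(tab$sample_id), function(s) {
        expr <- lapply(c("PR", "blh", "crtB", "crtY"), function(cl)
          tryCatch(transcript_relative_abundance(tab, s, cl),
                   error = function(e) NULL))
        expr <- Filter(Negate(is.null), expr)
        part <- tryCatch(color_transcript_partition(tab, s),
                         error = function(e) NULL)
        list(expression = expr, partition = part)
      })
      names(res) <- unique(tab$sample_id)
      ex_df <- do.call(rbind, lapply(res, function(r)
        do.call(rbind, lapply(r$expression, function(e)
          data.frame(sample_id = e$sample_id, gene_or_class = e$target,
                     relative_expression = e$relative_expression)))))
      outputs["transcription"] <<- wtab(ex_df, "expression.tsv")
      pt <- Filter(Negate(is.null), lapply(res, `[[`, "partition"))
      if (length(pt)) {
        pt_df <- do.call(rbind, lapply(pt, function(p)
          data.frame(sample_id = p$sample_id, blue_fraction = p$blue_fraction,
                     green_fraction = p$green_fraction,
                     unknown_mass = p$unknown_mass)))
        wtab(pt_df, "color_partition.tsv")
      }
      res
    })
  } else status["transcription"] <- "skipped"

  ## qpcr
  if (!is.null(config$qpcr_standards) && !is.null(config$qpcr_samples)) {
    results$qpcr <- run_stage("qpcr", function() {
      std <- utils::read.delim(config$qpcr_standards, stringsAsFactors = FALSE)
      smp <- utils::read.delim(config$qpcr_samples, stringsAsFactors = FALSE)
      curves <- lapply(split(std, std$assay_id), fit_standard_curve)
      cu_df <- do.call(rbind, lapply(names(curves), function(a)
        data.frame(assay_id = a, slope = curves[[a]]$slope,
                   intercept = curves[[a]]$intercept,
                   r_squared = curves[[a]]$r_squared,
                   efficiency = curves[[a]]$efficiency)))
      outputs["qpcr"] <<- wtab(cu_df, "standard_curves.tsv")
      meas <- list(); qrows <- list()
      for (key in unique(paste(smp$assay_id, smp$sample_id, sep = "\r"))) {
        parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
        sel <- smp$assay_id == parts[1] & smp$sample_id == parts[2]
        m <- quantify_copies(curves[[parts[1]]], smp$cq[sel],
                             assay_id = parts[1], sample_id = parts[2])
        meas[[key]] <- m
        qrows[[key]] <- data.frame(assay_id = m$assay_id, sample_id = m$sample_id,
                                   copies = m$copies, copies_cv = m$copies_cv)
      }
      q_df <- do.call(rbind, c(qrows, list(make.row.names = FALSE)))
      # per-taxon PR fractions against the 16S assay, plus their total
      fr <- list()
      for (s in unique(smp$sample_id)) {
        k16 <- paste("16S", s, sep = "\r")
        if (!k16 %in% names(meas)) next
        pr_assays <- setdiff(unique(smp$assay_id[smp$sample_id == s]), "16S")
        vals <- vapply(pr_assays, function(a) {
          r <- pr_relative_abundance(meas[[paste(a, s, sep = "\r")]], meas[[k16]])
          r$fraction
        }, 0)
        fr[[s]] <- data.frame(sample_id = s,
                              assay_id = c(pr_assays, "total_PR"),
                              fraction = c(vals, sum(vals, na.rm = TRUE)))
      }
      if (length(fr)) wtab(do.call(rbind, c(fr, list(make.row.names = FALSE))),
                           "qpcr_fractions.tsv")
      wtab(q_df, "qpcr_quantification.tsv")
      list(curves = curves, measurements = meas,
           fractions = if (length(fr)) do.call(rbind, fr) else NULL)
    })
  } else status["qpcr"] <- "skipped"

  manifest <- data.frame(stage = stages, status = unname(status),
                         output = unname(outputs), stringsAsFactors = FALSE)
  utils::write.table(manifest, out("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (length(warns)) writeLines(warns, out("warnings.log"))
  structure(list(manifest = manifest, results = results, outdir = outdir,
                 warnings = warns), class = "pipeline_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> output in", x$outdir, "\n")
  for (i in seq_len(nrow(x$manifest)))
    cat(sprintf("  %-14s %s\n", x$manifest$stage[i], x$manifest$status[i]))
  invisible(x)
}

#' Consolidated pipeline report
#'
#' Renders a human-readable summary of a pipeline run — per-sample PR-bearing
#' fraction, OTU shares, color partitions, relative expression, qPCR fractions
#' — plus a flags section (fractions above 1, below-detection assays). Also
#' writes the same numbers as a machine-readable TSV when \code{path} is given.
#'
#' @param run a \code{\link{run_pipeline}} result.
#' @param path optional file to write the report to (a TSV with suffix
#'   \code{"_summary.tsv"} is written alongside).
#' @return the report, invisibly, as a character vector of lines.
#' @export
pipeline_report <- function(run, path = NULL) {
  if (!any(run$manifest$status == "ok")) stop("empty run: no stage completed")
  lines <- c("proteorhodopsin pipeline report", "")
  summ <- list()
  add <- function(sample, metric, value)
    summ[[length(summ) + 1L]] <<- data.frame(sample_id = sample, metric = metric,
                                             value = value)
  flags <- character(0)
  if (!is.null(run$results$screen)) {
    sc <- run$results$screen$results
    lines <- c(lines, sprintf("screen: %d candidates, %d retained",
                              nrow(sc), sum(sc$retained)))
    add(NA, "n_candidates", nrow(sc)); add(NA, "n_retained", sum(sc$retained))
  }
  if (!is.null(run$results$cluster)) {
    lines <- c(lines, sprintf("cluster: %d OTUs at >= %.0f%% identity",
                              length(run$results$cluster$clusters),
                              100 * run$results$cluster$identity_threshold))
    add(NA, "n_otus", length(run$results$cluster$clusters))
  }
  if (!is.null(run$results$abundance)) {
    for (s in names(run$results$abundance)) {
      r <- run$results$abundance[[s]]
      lines <- c(lines, sprintf("metagenome %s: PR-bearing fraction %.4f%s",
                                s, r$fraction$pr_fraction,
                                if (r$fraction$flag_gt1) " [FLAG > 1]" else ""))
      if (r$fraction$flag_gt1) flags <- c(flags, paste0(s, ": PR fraction > 1"))
      add(s, "pr_fraction", r$fraction$pr_fraction)
      for (o in names(r$otu_shares)) {
        lines <- c(lines, sprintf("  %s share %.4f", o, r$otu_shares[[o]]))
        add(s, paste0("share_", o), r$otu_shares[[o]])
      }
    }
  } else lines <- c(lines, "metagenome: absent")
  if (!is.null(run$results$transcription)) {
    for (s in names(run$results$transcription)) {
      r <- run$results$transcription[[s]]
      for (e in r$expression) {
        lines <- c(lines, sprintf("metatranscriptome %s: %s relative expression %.4f",
                                  s, e$target, e$relative_expression))
        add(s, paste0("rel_expr_", e$target), e$relative_expression)
      }
      if (!is.null(r$partition)) {
        lines <- c(lines, sprintf("  blue PR transcript fraction %.4f (green %.4f)",
                                  r$partition$blue_fraction, r$partition$green_fraction))
        add(s, "blue_transcript_fraction", r$partition$blue_fraction)
      }
    }
  } else lines <- c(lines, "metatranscriptome: absent")
  if (!is.null(run$results$qpcr) && !is.null(run$results$qpcr$fractions)) {
    fr <- run$results$qpcr$fractions
    for (i in seq_len(nrow(fr))) {
      if (is.na(fr$fraction[i])) {
        lines <- c(lines, sprintf("qPCR %s %s: below detection",
                                  fr$sample_id[i], fr$assay_id[i]))
        flags <- c(flags, paste0(fr$sample_id[i], "/", fr$assay_id[i],
                                 ": below detection"))
      } else {
        lines <- c(lines, sprintf("qPCR %s %s: PR-bearing fraction %.4f%s",
                                  fr$sample_id[i], fr$assay_id[i], fr$fraction[i],
                                  if (fr$fraction[i] > 1) " [FLAG > 1]" else ""))
        if (fr$fraction[i] > 1)
          flags <- c(flags, paste0(fr$sample_id[i], "/", fr$assay_id[i],
                                   ": qPCR fraction > 1"))
        add(fr$sample_id[i], paste0("qpcr_fraction_", fr$assay_id[i]), fr$fraction[i])
      }
    }
  }
  lines <- c(lines, "", "flags:",
             if (length(flags)) paste(" -", flags) else " (none)")
  if (!is.null(path)) {
    writeLines(lines, path)
    utils::write.table(do.call(rbind, summ), sub("\\.[^.]*$", "_summary.tsv", path),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(lines)
}

#' Write a self-contained demo data set and pipeline configuration
#'
#' Generates, under \code{dir}, everything a full pipeline run needs: a
#' synthetic protein panel and candidate set (with one planted K108 variant),
#' metagenome and metatranscriptome count tables simulated from the default
#' community, simulated qPCR standards and samples, and a \code{config.yml}
#' pointing at them. Fully deterministic given \code{seed}.
#'
#' @param dir directory to populate (created if needed).
#' @param seed integer seed.
#' @return path to the written \code{config.yml}.
#' @export
write_demo_inputs <- function(dir, seed = 7L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_reference_panel(6, 4, 3, seed = seed)
  # plant a non-canonical pump variant (lysine at 108) among the candidates
  k108 <- mutate_positions(gen$panel[["green_PR_01"]], gen$reference, c("108" = "K"))
  k108$id <- "green_PR_01_K108"
  candidates <- c(gen$panel, stats::setNames(list(k108), k108$id))
  write_proteins(candidates, file.path(dir, "candidates.faa"))
  write_proteins(gen$panel[grep("PR", names(gen$panel))], file.path(dir, "panel.faa"))

  comm <- generate_community(default_community_spec())
  dna <- simulate_gene_counts(comm, depth = 1, seed = seed + 1L, sample_id = "Feb")
  rna <- simulate_transcript_counts(comm, depth = 1, seed = seed + 2L,
                                    sample_id = "Feb_day")
  utils::write.table(dna$counts, file.path(dir, "dna_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(rna$counts, file.path(dir, "rna_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  q <- simulate_qpcr_run(c(SAR11_PR = 1e4, SAR92_PR = 5e3, FlavoNASB_PR = 2e3,
                           "16S" = 1.9e5),
                         seed = seed + 3L)
  utils::write.table(q$standards, file.path(dir, "qpcr_standards.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(q$samples, file.path(dir, "qpcr_samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  config <- list(proteins = file.path(dir, "candidates.faa"),
                 panel = file.path(dir, "panel.faa"),
                 dna_counts = file.path(dir, "dna_counts.tsv"),
                 rna_counts = file.path(dir, "rna_counts.tsv"),
                 qpcr_standards = file.path(dir, "qpcr_standards.tsv"),
                 qpcr_samples = file.path(dir, "qpcr_samples.tsv"),
                 min_length_aa = 100L, identity_threshold = 0.82,
                 outdir = file.path(dir, "out"))
  yaml::write_yaml(config, file.path(dir, "config.yml"))
  file.path(dir, "config.yml")
}
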