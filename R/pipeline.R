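## End-to-end orchestration: filter -> map -> compare -> candidates,
## plus the calibration (cutoff scan), saturation, enrichment and
## 3'-proximity side analyses.  Every output is a schema-commented TSV
## (or YAML for the manifest) inside the chosen output directory, and
## all randomness funnels through the single seed recorded there.

#' Run the DGE tag-profiling pipeline
#'
#' Runs the full analysis either on a simulated study (the default: a
#' [synthetic_config()] generates the reference, genome, annotations and
#' libraries) or on user-supplied inputs.  Stages: load/simulate inputs;
#' build theoretical tag indexes; filter libraries at the occurrence
#' cutoff and normalise to cpm; map the pooled distinct tags against
#' every reference set (mapping summaries and reference overlap);
#' binomial comparisons against the reference fraction with splashplot
#' coordinates; fraction assignment of candidate tags; inter-fraction
#' correlations; cutoff specificity scan; saturation curves; optional GO
#' enrichment of fraction-specific transcript sets and 3'-UTR proximity
#' profile.  A failure in any stage aborts with the stage name; outputs
#' of completed stages are preserved.
#'
#' @param out_dir output directory (created if needed).
#' @param synthetic a [synthetic_config()] used when no libraries are
#'   supplied; ignored otherwise.
#' @param libraries named list of [tag_library()] objects or TSV paths.
#' @param references named list of reference sequence sets
#'   ([Biostrings::DNAStringSet], named character or FASTA paths).
#' @param genome optional genome sequence set (same types as
#'   `references`).
#' @param annotations optional named list (id -> terms) or annotation TSV
#'   path; `edges` the matching ontology edges (data.frame or TSV path).
#' @param edges see `annotations`.
#' @param cutoff occurrence cutoff for reliable tags (default 5).
#' @param de_alpha significance level for differential-expression
#'   candidate selection (default 0.001).
#' @param go_alpha significance level for term enrichment (default 1e-5).
#' @param n_rand randomized replicates for the cutoff scan.
#' @param saturation_step subsampling step in reads.
#' @param window half-width for the 3'-proximity profile.
#' @param seed master seed for every stochastic stage.
#' @return (invisibly) a list with every stage result and the manifest.
#' @export
run_dge_pipeline <- function(out_dir,
                             synthetic = synthetic_config(),
                             libraries = NULL,
                             references = NULL,
                             genome = NULL,
                             annotations = NULL,
                             edges = NULL,
                             cutoff = 5,
                             de_alpha = 0.001,
                             go_alpha = 1e-5,
                             n_rand = 20,
                             saturation_step = 200000,
                             window = 1000,
                             seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  res <- list()

  inputs <- stage("inputs", {
    if (is.null(libraries)) {
      cfg <- synthetic
      cfg$seed <- as.integer(seed)
      study <- generate_transcriptome(cfg)
      gen <- generate_genome(study, seed = seed + 11L)
      libs <- lapply(names(cfg$library_depths), function(s)
        simulate_dge_library(study, s, cfg))
      names(libs) <- names(cfg$library_depths)
      refs <- list(transcriptome = reference_sequences(study))
      ann <- simulate_go_annotations(study, seed = seed + 13L)
      writeXStringSet(refs$transcriptome,
                      file.path(out_dir, "reference.fasta"))
      writeXStringSet(gen$genome, file.path(out_dir, "genome.fasta"))
      write_placements_gff3(gen$placements,
                            file.path(out_dir, "placements.gff3"))
      write_truth_yaml(study$truth, file.path(out_dir, "truth.yaml"))
      for (s in names(libs))
        write_tag_library(libs[[s]],
                          file.path(out_dir, paste0("library_", s, ".tsv")))
      list(libraries = libs, references = refs, genome = gen$genome,
           annotations = ann$direct, edges = ann$edges,
           truth = study$truth, placements_truth = gen$placements)
    } else {
      libs <- lapply(libraries, function(x)
        if (inherits(x, "tag_library")) x else read_tag_library(x))
      if (is.null(names(libs)))
        names(libs) <- vapply(libs, `[[`, "", "sample_id")
      refs <- lapply(references, function(x)
        if (is.character(x) && length(x) == 1 && file.exists(x))
          readDNAStringSet(x) else x)
      if (is.character(annotations))
        annotations <- read_annotations(annotations)
      if (is.character(edges)) edges <- read_ontology_edges(edges)
      list(libraries = libs, references = refs, genome = genome,
           annotations = annotations, edges = edges,
           truth = NULL, placements_truth = NULL)
    }
  })
  libraries <- inputs$libraries
  references <- inputs$references
  genome <- inputs$genome
  annotations <- inputs$annotations
  edges <- inputs$edges
  res$truth <- inputs$truth
  res$placements_truth <- inputs$placements_truth

  indexes <- stage("index", {
    ix <- lapply(names(references), function(nm)
      build_tag_index(references[[nm]], name = nm))
    names(ix) <- names(references)
    if (!is.null(genome))
      ix$genome <- build_tag_index(genome, name = "genome")
    ix
  })

  filtered <- stage("filter", {
    lapply(libraries, filter_by_cutoff, min_count = cutoff)
  })
  cpm <- lapply(filtered, normalize_cpm)

  ## pooled distinct tags passing the cutoff in any library
  pooled <- stage("pool", {
    all_counts <- unlist(lapply(filtered, function(l) l$counts))
    tagnames <- unlist(lapply(filtered, function(l) names(l$counts)))
    tot <- tapply(all_counts, tagnames, sum)
    tag_library(setNames(as.integer(tot), names(tot)),
                sample_id = "pooled",
                total_reads = sum(vapply(libraries, `[[`, 0, "total_reads")))
  })

  mappings <- stage("map", {
    ## the 3'-most rule resolves tags within a transcript; genome contigs
    ## hold many transcripts, so no positional resolution applies there
    mp <- lapply(indexes, function(ix)
      map_tags_exact(pooled, ix, resolve_3prime = ix$name != "genome"))
    msum <- do.call(rbind, lapply(mp, summarize_mapping))
    write_tsv_schema(msum, file.path(out_dir, "mapping_summary.tsv"))
    write_tsv_schema(reference_overlap(mp),
                     file.path(out_dir, "reference_overlap.tsv"))
    attr(mp, "summary") <- msum
    mp
  })
  res$mapping_summary <- attr(mappings, "summary")

  comparisons <- stage("compare", {
    samples <- names(cpm)
    ref_fraction <- samples[length(samples)]
    tags <- Reduce(union, lapply(cpm, names))
    m <- vapply(cpm, function(v)
      ifelse(tags %in% names(v), v[tags], 0), numeric(length(tags)))
    rownames(m) <- tags
    tab <- data.frame(tag = tags, round(m[, samples, drop = FALSE], 4))
    for (s in setdiff(samples, ref_fraction)) {
      cmp <- compare_libraries(m[, s], m[, ref_fraction], tags = tags)
      tab[[paste0("p_", s, "_", ref_fraction)]] <- cmp$p_value
    }
    if (all(c("X1", "X2", "Xin") %in% samples)) {
      sp <- splash_coordinates(m[, "X1"], m[, "X2"], m[, "Xin"],
                               tags = tags)
      tab$splash_x <- sp$x; tab$splash_y <- sp$y
      tab$quadrant <- sp$quadrant
    }
    write_tsv_schema(tab, file.path(out_dir, "expression.tsv"))
    list(table = tab, cpm_matrix = m, ref_fraction = ref_fraction)
  })

  candidates <- stage("candidates", {
    fa <- fraction_assignments(comparisons$cpm_matrix, alpha = de_alpha)
    write_tsv_schema(fa[fa$significant, ],
                     file.path(out_dir, "candidates.tsv"))
    fa
  })

  correlations <- stage("correlate", {
    shared <- Reduce(intersect, lapply(cpm, names))
    co <- if (length(shared) >= 3) {
      m <- vapply(cpm, function(v) v[shared], numeric(length(shared)))
      correlate_fractions(m)
    } else NULL
    if (!is.null(co)) {
      df <- data.frame(pair = outer(colnames(co$pearson),
                                    colnames(co$pearson), paste,
                                    sep = "-")[upper.tri(co$pearson)],
                       pearson = co$pearson[upper.tri(co$pearson)],
                       spearman = co$spearman[upper.tri(co$spearman)])
      write_tsv_schema(df, file.path(out_dir, "correlations.tsv"))
    }
    co
  })

  cutoff_scan <- stage("cutoff-scan", {
    main_ix <- indexes[[1]]
    scans <- lapply(names(libraries), function(s) {
      sc <- specificity_scan(libraries[[s]], main_ix, n_rand = n_rand,
                             seed = seed + 17L)
      sc$sample <- s
      sc$recommended <- recommend_cutoff(sc)
      sc
    })
    tab <- do.call(rbind, scans)
    write_tsv_schema(tab, file.path(out_dir, "cutoff_scan.tsv"))
    tab
  })

  saturation <- stage("saturate", {
    sat <- saturation_curve(pooled, indexes, step = saturation_step,
                            seed = seed + 19L)
    write_tsv_schema(as.data.frame(sat),
                     file.path(out_dir, "saturation.tsv"))
    sat
  })

  enrichment <- NULL
  if (!is.null(annotations) && !is.null(edges)) {
    enrichment <- stage("enrich", {
      prop <- propagate_annotations(annotations, edges)
      first_map <- mappings[[1]]
      sense_hits <- first_map$hits[first_map$hits$strand == "+", ]
      tag2seq <- split(sense_hits$reference_id, sense_hits$tag)
      sig <- candidates[candidates$significant, ]
      study_sets <- lapply(split(sig$tag, sig$fraction), function(tt)
        intersect(unique(unlist(tag2seq[tt])), names(prop)))
      study_sets <- study_sets[lengths(study_sets) > 0]
      en <- enrich_fraction_sets(study_sets, prop, alpha = go_alpha)
      write_tsv_schema(en, file.path(out_dir, "enrichment.tsv"))
      en
    })
  }

  proximity <- NULL
  if (!is.null(genome)) {
    proximity <- stage("utr3", {
      ## tags mapping to the genome but to no transcript set
      txp_sets <- setdiff(names(mappings), "genome")
      orphan_everywhere <- Reduce(intersect, lapply(
        mappings[txp_sets], function(m)
          m$records$tag[m$records$status == "orphan"]))
      gmap <- mappings$genome
      gonly <- gmap$hits[gmap$hits$tag %in% orphan_everywhere, ]
      pl <- place_transcripts(references[[1]], genome)
      prof <- proximity_profile(pl$placements, gonly, window = window,
                                genome = genome)
      write_tsv_schema(prof$histogram,
                       file.path(out_dir, "utr_proximity.tsv"))
      prof
    })
  }

  manifest <- list(
    package = as.character(packageVersion("tagdge")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    parameters = list(cutoff = cutoff, de_alpha = de_alpha,
                      go_alpha = go_alpha, n_rand = n_rand,
                      saturation_step = saturation_step, window = window),
    libraries = lapply(libraries, function(l)
      list(sample_id = l$sample_id, distinct_tags = length(l$counts),
           total_reads = l$total_reads)),
    reference_sets = names(indexes),
    recommended_cutoff = unique(cutoff_scan$recommended))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  res <- c(res, list(
    libraries = libraries, filtered = filtered, cpm = cpm,
    pooled = pooled, indexes = indexes, mappings = mappings,
    comparisons = comparisons, candidates = candidates,
    correlations = correlations, cutoff_scan = cutoff_scan,
    saturation = saturation, enrichment = enrichment,
    proximity = proximity, manifest = manifest, out_dir = out_dir))
  invisible(res)
}

#' Render report figures for a pipeline run
#'
#' Draws the saturation curves (one series per reference set) and, when
#' three-fraction splash coordinates are present, the splashplot
#' projection, saving both as PDF files in the run directory.
#'
#' @param run_dir a directory produced by [run_dge_pipeline()].
#' @return (invisibly) the paths of the figures written.
#' @export
dge_report <- function(run_dir) {
  sat_path <- file.path(run_dir, "saturation.tsv")
  expr_path <- file.path(run_dir, "expression.tsv")
  for (p in c(sat_path, expr_path))
    if (!file.exists(p))
      stop("missing pipeline output: ", p,
           " (run run_dge_pipeline() first)")
  sat <- read.table(sat_path, header = TRUE, sep = "\t",
                    comment.char = "#")
  expr <- read.table(expr_path, header = TRUE, sep = "\t",
                     comment.char = "#")
  if (nrow(expr) == 0) stop("expression table is empty: ", expr_path)
  paths <- character(0)
  p1 <- ggplot2::ggplot(sat, ggplot2::aes(x = subsample_size,
                                          y = distinct_mapped,
                                          colour = reference_set)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "subsampled reads", y = "distinct mapped tags",
                  colour = "reference set",
                  title = "Saturation of distinct mapped tags") +
    ggplot2::theme_minimal()
  f1 <- file.path(run_dir, "saturation_plot.pdf")
  ggplot2::ggsave(f1, p1, width = 7, height = 5)
  paths <- c(paths, f1)
  if (all(c("splash_x", "splash_y", "quadrant") %in% names(expr))) {
    p2 <- ggplot2::ggplot(expr, ggplot2::aes(x = splash_x, y = splash_y,
                                             colour = quadrant)) +
      ggplot2::geom_point(alpha = 0.5, size = 0.8) +
      ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
      ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
      ggplot2::labs(x = "signed log2 |X1 - Xin|",
                    y = "signed log2 |X2 - Xin|",
                    title = "Splashplot projection") +
      ggplot2::theme_minimal()
    f2 <- file.path(run_dir, "splashplot.pdf")
    ggplot2::ggsave(f2, p2, width = 6, height = 6)
    paths <- c(paths, f2)
  }
  invisible(paths)
}
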