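#' Pipeline configuration
#'
#' Collects every stage parameter of [run_pipeline()] into one
#' serialisable object, so a report can embed the exact configuration
#' that produced it. Either `input` (a file path, read according to
#' `format`) or `corpus` (an in-memory corpus tibble) must be supplied.
#'
#' @param input Optional path to a corpus file.
#' @param format `"tsv"` ([read_doc_term_tsv()]) or `"xml"`
#'   ([read_medline_xml()]).
#' @param corpus Optional in-memory corpus tibble (overrides `input`).
#' @param check_tags `NULL` for the shipped default list, a character
#'   vector of tags, or `FALSE` to skip check-tag removal.
#' @param major_only Restrict to major-topic terms before counting.
#' @param critical_value,positive_only,yates_threshold Chi-square filter
#'   settings, see [filter_network()].
#' @param sample_sources,sample_nodes Sampling controls for the topology
#'   stage (auto-enabled on graphs with more than 2000 nodes).
#' @param replicates Erdős–Rényi baseline replicates.
#' @param n_boot Bootstrap replicates for the degree-distribution fits.
#' @param min_tail Minimum tail size for kmin candidates.
#' @param attack_fraction Fraction of nodes removed per attack.
#' @param top_terms Number of top-degree terms listed in the report.
#' @param seed Master seed; all stage seeds are sub-streams of it.
#' @param output_dir Optional directory for `report.json` / `report.md`.
#' @return A list of class `conet_config`.
#' @export
conet_config <- function(input = NULL, format = c("tsv", "xml"), corpus = NULL,
                         check_tags = NULL, major_only = FALSE,
                         critical_value = 3.84, positive_only = TRUE,
                         yates_threshold = 5, sample_sources = NULL,
                         sample_nodes = NULL, replicates = 10, n_boot = 200,
                         min_tail = 10, attack_fraction = 0.10,
                         top_terms = 50, seed = 1, output_dir = NULL) {
  format <- match.arg(format)
  if (is.null(input) && is.null(corpus)) {
    abort("Supply either `input` (a file path) or `corpus` (a corpus tibble).")
  }
  structure(
    list(input = input, format = format, corpus = corpus,
         check_tags = check_tags, major_only = major_only,
         critical_value = critical_value, positive_only = positive_only,
         yates_threshold = yates_threshold, sample_sources = sample_sources,
         sample_nodes = sample_nodes, replicates = replicates,
         n_boot = n_boot, min_tail = min_tail,
         attack_fraction = attack_fraction, top_terms = top_terms,
         seed = seed, output_dir = output_dir),
    class = "conet_config"
  )
}

#' Read and write pipeline configurations as JSON
#'
#' @param config A [conet_config()].
#' @param path File path.
#' @return `read_conet_config()` returns a `conet_config`.
#' @export
write_conet_config <- function(config, path) {
  stopifnot(inherits(config, "conet_config"))
  cfg <- config[setdiff(names(config), "corpus")]
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(config)
}

#' @rdname write_conet_config
#' @export
read_conet_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(conet_config, cfg)
}

run_stage <- function(stage, partial, output_dir, expr) {
  tryCatch(expr, error = function(e) {
    if (!is.null(output_dir)) {
      dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
      jsonlite::write_json(
        report_to_json_list(partial),
        file.path(output_dir, "report_partial.json"),
        auto_unbox = TRUE, null = "null", digits = NA, force = TRUE
      )
    }
    abort(sprintf("Pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

report_to_json_list <- function(report) {
  lapply(report, function(x) {
    if (inherits(x, "powerlaw_fit")) return(as.list(glance(x)))
    if (inherits(x, "conet_config")) return(x[setdiff(names(x), "corpus")])
    x
  })
}

#' Run the full co-occurrence network analysis pipeline
#'
#' Ingest -> check-tag removal -> (optional) major restriction ->
#' co-occurrence counting -> chi-square filtering -> giant component ->
#' topology summary + Erdős–Rényi baseline + small-world index ->
#' power-law and alternative degree-distribution fits -> degree,
#' betweenness and random attacks -> top-degree term table. Counts are
#' reported after every reduction step so runs on real data can be
#' compared step by step. With the same configuration (and seed) the
#' emitted JSON report is byte-identical across runs.
#'
#' @param config A [conet_config()].
#' @return A list of class `conet_report` with elements `config`, `counts`,
#'   `topology`, `baseline`, `small_world`, `powerlaw`, `alternatives`,
#'   `attacks`, `top_terms`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "conet_config"))
  cfg <- config
  report <- list(config = cfg)
  out_dir <- cfg$output_dir

  corpus <- run_stage("ingest", report, out_dir, {
    corp <- if (!is.null(cfg$corpus)) {
      as_corpus(cfg$corpus)
    } else if (cfg$format == "xml") {
      read_medline_xml(cfg$input)
    } else {
      read_doc_term_tsv(cfg$input)
    }
    if (nrow(corp) == 0) abort("Corpus is empty after ingest.")
    corp
  })
  counts_tbl <- tibble(stage = "ingest", n_docs = n_docs(corpus),
                       n_terms = length(vocabulary(corpus)), n_edges = NA_real_)

  corpus <- run_stage("check_tags", report, out_dir, {
    if (isFALSE(cfg$check_tags)) {
      corpus
    } else {
      tags <- if (is.null(cfg$check_tags)) default_check_tags() else cfg$check_tags
      filter_check_tags(corpus, tags)
    }
  })
  counts_tbl <- bind_rows(counts_tbl,
    tibble(stage = "check_tags_removed", n_docs = n_docs(corpus),
           n_terms = length(vocabulary(corpus)), n_edges = NA_real_))

  if (cfg$major_only) {
    corpus <- run_stage("ingest", report, out_dir, {
      corp <- restrict_major(corpus)
      if (nrow(corp) == 0) {
        abort("major_only = TRUE but the corpus has no major-topic descriptors.")
      }
      corp
    })
    counts_tbl <- bind_rows(counts_tbl,
      tibble(stage = "major_only", n_docs = n_docs(corpus),
             n_terms = length(vocabulary(corpus)), n_edges = NA_real_))
  }

  pc <- run_stage("count", report, out_dir, count_pairs(corpus))
  counts_tbl <- bind_rows(counts_tbl,
    tibble(stage = "cooccurrence", n_docs = pc$n_docs,
           n_terms = nrow(pc$doc_freq), n_edges = as.double(nrow(pc$pair_freq))))
  net <- run_stage("filter", report, out_dir, {
    filter_network(pc, critical_value = cfg$critical_value,
                   positive_only = cfg$positive_only,
                   yates_threshold = cfg$yates_threshold)
  })
  counts_tbl <- bind_rows(counts_tbl,
    tibble(stage = "chi_square_filtered", n_docs = NA_integer_,
           n_terms = length(net$nodes), n_edges = as.double(nrow(net$edges))))

  gc <- run_stage("giant_component", report, out_dir, {
    giant_component(as_conet_igraph(net))
  })
  counts_tbl <- bind_rows(counts_tbl,
    tibble(stage = "giant_component", n_docs = NA_integer_,
           n_terms = igraph::vcount(gc), n_edges = as.double(igraph::ecount(gc))))
  report$counts <- counts_tbl

  report$topology <- run_stage("topology", report, out_dir, {
    topology_summary(gc, sample_sources = cfg$sample_sources,
                     sample_nodes = cfg$sample_nodes, seed = sub_seed(cfg$seed, 11))
  })

  report$baseline <- run_stage("baseline", report, out_dir, {
    bl <- er_baseline(igraph::vcount(gc), igraph::ecount(gc),
                      replicates = cfg$replicates, seed = sub_seed(cfg$seed, 12),
                      sample_sources = cfg$sample_sources,
                      sample_nodes = cfg$sample_nodes)
    attr(bl, "detail") <- NULL
    bl
  })

  report$small_world <- run_stage("small_world", report, out_dir, {
    small_world_index(report$topology$clustering, report$baseline$c_r,
                      report$topology$path_length, report$baseline$l_r)
  })

  report$assortativity <- run_stage("assortativity", report, out_dir, {
    tibble(r = suppressWarnings(degree_assortativity(gc)))
  })

  degs <- degree_sequence(gc)$degree
  report$powerlaw <- run_stage("degree_fit", report, out_dir, {
    fit <- tryCatch(
      fit_power_law_tail(degs, min_tail = cfg$min_tail, n_boot = cfg$n_boot,
                         seed = sub_seed(cfg$seed, 13)),
      error = function(e) NULL
    )
    if (is.null(fit)) NULL else glance(fit)
  })

  report$alternatives <- run_stage("degree_fit", report, out_dir, {
    if (is.null(report$powerlaw)) {
      NULL
    } else {
      alt <- fit_alternatives(degs, kmin = report$powerlaw$kmin,
                              n_boot = cfg$n_boot, seed = sub_seed(cfg$seed, 14))
      select(alt, -"params")
    }
  })

  report$attacks <- run_stage("attack", report, out_dir, {
    bind_rows(
      attack(gc, "degree", fraction = cfg$attack_fraction),
      attack(gc, "betweenness", fraction = cfg$attack_fraction,
             seed = sub_seed(cfg$seed, 15)),
      attack(gc, "random", fraction = cfg$attack_fraction,
             seed = sub_seed(cfg$seed, 16))
    )
  })

  report$top_terms <- run_stage("report", report, out_dir, {
    degree_sequence(gc) %>%
      arrange(dplyr::desc(.data$degree), .data$node) %>%
      head(cfg$top_terms)
  })

  class(report) <- "conet_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.conet_report <- function(x, ...) {
  cat("<conet_report>\n\nReduction steps:\n")
  print(as.data.frame(x$counts), row.names = FALSE)
  cat("\nTopology:\n")
  print(as.data.frame(x$topology), row.names = FALSE)
  cat("\nRandom baseline:\n")
  print(as.data.frame(x$baseline), row.names = FALSE)
  cat(sprintf("\nSmall-world index: sigma = %.3f (%s)\n",
              x$small_world$sigma,
              if (x$small_world$is_small_world) "small-world" else "not small-world"))
  if (!is.null(x$powerlaw)) {
    cat(sprintf("Power-law tail: alpha = %.3f, kmin = %d, KS = %.4f, p = %s\n",
                x$powerlaw$alpha, x$powerlaw$kmin, x$powerlaw$ks,
                format(x$powerlaw$p_value)))
  }
  cat("\nAttacks:\n")
  print(as.data.frame(x$attacks), row.names = FALSE)
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (machine-readable, embeds the configuration) and
#' `report.md` (human-readable summary tables).
#'
#' @param report A `conet_report`.
#' @param dir Output directory (created if absent).
#' @return The report, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "conet_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_to_json_list(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, null = "null", digits = NA, force = TRUE)
  md <- c(
    "# Co-occurrence network analysis report", "",
    "## Reduction steps", "",
    knit_md_table(report$counts), "",
    "## Topology", "",
    knit_md_table(report$topology), "",
    "## Random baseline", "",
    knit_md_table(report$baseline), "",
    "## Small world", "",
    knit_md_table(report$small_world), "",
    "## Degree distribution", "",
    if (!is.null(report$powerlaw)) knit_md_table(report$powerlaw) else "(no power-law fit)", "",
    if (!is.null(report$alternatives)) knit_md_table(report$alternatives) else NULL, "",
    "## Attacks", "",
    knit_md_table(report$attacks), "",
    "## Top-degree terms", "",
    knit_md_table(report$top_terms)
  )
  writeLines(md, file.path(dir, "report.md"))
  invisible(report)
}

knit_md_table <- function(df) {
  df <- as.data.frame(df)
  if (nrow(df) == 0) return("(empty)")
  fmt <- vapply(df, function(col) format(col, trim = TRUE), character(nrow(df)))
  fmt <- matrix(fmt, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(fmt, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}
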