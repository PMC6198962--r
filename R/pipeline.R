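# End-to-end orchestration: validated config, staged analyses, report
# bundle with a machine-readable run manifest.

#' Validate a pipeline configuration
#'
#' Checks the whole configuration up front and reports every violation at
#' once; no analysis starts from an invalid config.
#'
#' @param config Named list (or path to a YAML file) with entries:
#'   \code{input} (either \code{digest_table}, or \code{sequences} = named
#'   region -> FASTA path map plus \code{sample_sheet}), \code{panel}
#'   (\code{"4site"}, \code{"12site"} or a TSV path with columns
#'   region/enzyme/column), \code{analyses} (subset of frequencies, chisq,
#'   amova, discover, network), and optional \code{enzymes} (YAML catalog
#'   path), \code{metric}, \code{n_perm}, \code{seed}, \code{max_mismatch},
#'   \code{out_dir}.
#' @return The normalised config (invisibly for \code{validate_config}).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)

  inp <- config$input
  if (is.null(inp)) {
    note("input: missing")
  } else if (!is.null(inp$digest_table)) {
    if (!file.exists(inp$digest_table)) {
      note(paste0("input$digest_table: file not found: ", inp$digest_table))
    }
  } else if (!is.null(inp$sequences)) {
    for (reg in names(inp$sequences)) {
      if (!file.exists(inp$sequences[[reg]])) {
        note(paste0("input$sequences$", reg, ": file not found: ",
                    inp$sequences[[reg]]))
      }
    }
    if (is.null(inp$sample_sheet)) {
      note("input$sample_sheet: required with sequence input")
    } else if (!file.exists(inp$sample_sheet)) {
      note(paste0("input$sample_sheet: file not found: ", inp$sample_sheet))
    }
  } else {
    note("input: needs either digest_table or sequences")
  }

  config$analyses <- config$analyses %||%
    c("frequencies", "chisq", "amova", "network")
  known <- c("frequencies", "chisq", "amova", "discover", "network")
  bad <- setdiff(config$analyses, known)
  if (length(bad)) note(paste0("analyses: unknown: ", paste(bad, collapse = ", ")))
  if ("discover" %in% config$analyses && is.null(inp$sequences)) {
    note("analyses: 'discover' requires sequence input")
  }

  config$panel <- config$panel %||% "4site"
  if (!config$panel %in% c("4site", "12site") && !file.exists(config$panel)) {
    note(paste0("panel: not '4site', '12site' or an existing file: ",
                config$panel))
  }
  if (!is.null(config$enzymes) && !file.exists(config$enzymes)) {
    note(paste0("enzymes: file not found: ", config$enzymes))
  }
  config$metric <- config$metric %||% "hamming"
  if (!config$metric %in% c("hamming", "nei")) {
    note(paste0("metric: must be hamming or nei, got ", config$metric))
  }
  config$n_perm <- config$n_perm %||% 999L
  if (config$n_perm < 0) note("n_perm: must be >= 0")
  config$seed <- config$seed %||% 1L
  config$max_mismatch <- config$max_mismatch %||% 1L
  config$out_dir <- config$out_dir %||% "chlorotypr_out"

  if (length(problems)) {
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  }
  invisible(config)
}

resolve_panel <- function(panel_field) {
  if (identical(panel_field, "4site")) return(panel_4site())
  if (identical(panel_field, "12site")) return(panel_12site())
  df <- utils::read.table(panel_field, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  chlorotype_panel(df, name = basename(panel_field))
}

# Hash of the analytic configuration: the output location does not change
# what is computed, so it is excluded and identical analyses hash alike.
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  analytic <- config[setdiff(names(config), "out_dir")]
  analytic <- analytic[order(names(analytic))]
  writeLines(jsonlite::toJSON(analytic, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

write_report <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the chlorotyping pipeline
#'
#' Loads the configured inputs (a digest-call table, or per-region FASTA
#' files typed against the panel), runs the requested analyses, and writes
#' a report bundle to the output directory: \code{frequencies.tsv},
#' \code{chisq.tsv}, \code{amova.tsv}, \code{sites.tsv},
#' \code{network_edges.tsv} / \code{network_nodes.tsv} /
#' \code{network.graphml}, plus \code{manifest.json} recording the config
#' hash, package version, seed and every parameter. Re-running the same
#' config over the same inputs reproduces the bundle byte for byte.
#'
#' @param config Config list or YAML path; see \code{\link{validate_config}}.
#' @return Invisible named list of written report paths.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  hash <- config_hash(config)
  panel <- resolve_panel(config$panel)
  catalog <- if (is.null(config$enzymes)) default_enzyme_catalog() else
    read_enzyme_catalog(config$enzymes)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  alignments <- NULL

  if (!is.null(config$input$digest_table)) {
    dataset <- read_digest_table(config$input$digest_table, panel = panel)
  } else {
    alignments <- lapply(config$input$sequences, read_sequences)
    sheet <- utils::read.table(config$input$sample_sheet, sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE)
    chl <- type_sequences(alignments, panel, catalog)
    dataset <- grouped_dataset(sheet$sample_id, sheet$group,
                               unname(chl[sheet$sample_id]), panel = panel)
  }

  if ("frequencies" %in% config$analyses) {
    freq <- tabulate_frequencies(dataset)
    paths$frequencies <- write_report(
      freq, file.path(config$out_dir, "frequencies.tsv"), hash)
  }
  if ("chisq" %in% config$analyses) {
    ct <- contingency_table(dataset)
    res <- pearson_chisq(ct)
    paths$chisq <- write_report(
      data.frame(statistic = res$statistic, df = res$df,
                 p_value = res$p_value),
      file.path(config$out_dir, "chisq.tsv"), hash)
  }
  if ("amova" %in% config$analyses) {
    res <- amova(drop_inconclusive(dataset), distance = config$metric,
                 n_perm = config$n_perm, seed = config$seed)
    comp <- data.frame(
      component = c("among_groups", "within_groups", "total"),
      ssd = c(res$ssd_among, res$ssd_within, res$ssd_total),
      df = c(res$df_among, res$df_within, res$df_among + res$df_within),
      sigma2 = c(res$sigma2_among, res$sigma2_within, NA),
      pct = c(res$pct_among, res$pct_within, NA),
      p_perm = c(res$p_perm, NA, NA))
    contrib <- data.frame(component = paste0("within:", names(res$within_contributions)),
                          ssd = NA, df = NA, sigma2 = NA,
                          pct = unname(res$within_contributions), p_perm = NA)
    paths$amova <- write_report(rbind(comp, contrib),
                                file.path(config$out_dir, "amova.tsv"), hash)
  }
  if ("discover" %in% config$analyses) {
    sites <- discover_informative_digests(alignments, catalog,
                                          exclude = panel)
    paths$sites <- write_report(
      sites, file.path(config$out_dir, "sites.tsv"), hash)
  }
  if ("network" %in% config$analyses) {
    kept <- drop_inconclusive(dataset)
    freqs <- table(kept$chlorotype)
    D <- chlorotype_distances(names(freqs), metric = config$metric)
    net <- minimum_spanning_network(D, node_freqs = freqs)
    cent <- eigenvector_centrality(net)
    net$nodes$centrality <- unname(cent[net$nodes$label])
    write_network_tables(net,
                         edge_path = file.path(config$out_dir,
                                               "network_edges.tsv"),
                         node_path = file.path(config$out_dir,
                                               "network_nodes.tsv"))
    write_graphml(net, file.path(config$out_dir, "network.graphml"))
    paths$network_edges <- file.path(config$out_dir, "network_edges.tsv")
    paths$network_nodes <- file.path(config$out_dir, "network_nodes.tsv")
    paths$network_graphml <- file.path(config$out_dir, "network.graphml")
  }

  manifest <- list(
    config_hash = hash,
    package_version = as.character(utils::packageVersion("chlorotypr")),
    config = config,
    reports = lapply(paths, normalizePath)
  )
  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths$manifest <- mpath
  invisible(paths)
}
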