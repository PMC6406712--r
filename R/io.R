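#' File interchange for study artifacts
#'
#' Plain-text readers and writers for the pipeline's on-disk formats:
#' sample metadata and wide feature tables as comma- or tab-separated text
#' (delimiter sniffed on read), spectral libraries in the NIST MSP dialect,
#' pathway sets as GMT plus an edge list, and ground truth / configuration
#' as JSON. All writers are deterministic: identical inputs give
#' byte-identical files.
#'
#' @name csfmet-io
NULL

#' @noRd
sniff_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (lengths(regmatches(line, gregexpr("\t", line))) > 0) "\t" else ","
}

#' @rdname csfmet-io
#' @param cohort,path see details; `path` is a file path.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname csfmet-io
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, sep = sniff_sep(path), stringsAsFactors = FALSE,
                 na.strings = c("NA", ""))
  df$group <- factor(df$group, levels = c("control", "RRMS", "SPMS"))
  df
}

#' @rdname csfmet-io
#' @param table an [injection_table()].
#' @param features_path,injections_path output paths for the wide feature
#'   table (`feature_id`, `mz`, `rt`, one column per injection) and the
#'   injection metadata.
#' @export
write_injection_table <- function(table, features_path, injections_path) {
  wide <- cbind(table$feature_meta[, c("feature_id", "mz", "rt")],
                as.data.frame(table$intensities, check.names = FALSE))
  write.csv(wide, features_path, row.names = FALSE, quote = FALSE, na = "")
  write.csv(table$injections, injections_path, row.names = FALSE,
            quote = FALSE, na = "")
  invisible(features_path)
}

#' @rdname csfmet-io
#' @export
read_injection_table <- function(features_path, injections_path) {
  wide <- read.csv(features_path, sep = sniff_sep(features_path),
                   check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  inj <- read.csv(injections_path, sep = sniff_sep(injections_path),
                  stringsAsFactors = FALSE, na.strings = c("NA", ""))
  meta_cols <- c("feature_id", "mz", "rt")
  M <- as.matrix(wide[, setdiff(names(wide), meta_cols), drop = FALSE])
  rownames(M) <- wide$feature_id
  M <- M[, inj$injection_id, drop = FALSE]
  injection_table(M, inj, wide[, meta_cols])
}

#' @rdname csfmet-io
#' @param library a `spectral_library`.
#' @export
write_msp <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  e <- library$entries
  for (i in seq_len(nrow(e))) {
    cat(sprintf("Name: %s\n", e$name[i]), file = con)
    if (!is.na(e$kegg_id[i]))
      cat(sprintf("KEGG: %s\n", e$kegg_id[i]), file = con)
    cat(sprintf("PrecursorMZ: %.4f\n", e$mz[i]), file = con)
    cat(sprintf("RT: %.1f\n", e$rt[i]), file = con)
    cat(sprintf("Adduct: %s\n", e$adduct[i]), file = con)
    pk <- library$ms2[[i]]
    cat(sprintf("Num Peaks: %d\n", if (is.null(pk)) 0L else nrow(pk)),
        file = con)
    if (!is.null(pk))
      cat(sprintf("%.4f %.1f", pk[, 1], pk[, 2]), sep = "\n", file = con)
    cat("\n", file = con)
  }
  invisible(path)
}

#' @rdname csfmet-io
#' @export
read_msp <- function(path) {
  lines <- readLines(path)
  entries <- list(); ms2 <- list(); cur <- list(); peaks <- NULL
  flush_entry <- function() {
    if (is.null(cur$name)) return()
    entries[[length(entries) + 1L]] <<-
      data.frame(name = cur$name, kegg_id = cur$kegg %||% NA_character_,
                 mz = cur$mz, rt = cur$rt %||% NA_real_,
                 adduct = cur$adduct %||% NA_character_,
                 stringsAsFactors = FALSE)
    ms2[[length(ms2) + 1L]] <<-
      if (is.null(peaks)) NULL else
        matrix(peaks, ncol = 2, byrow = TRUE,
               dimnames = list(NULL, c("mz", "intensity")))
  }
  for (ln in lines) {
    if (grepl("^Name:", ln)) {
      flush_entry(); cur <- list(); peaks <- NULL
      cur$name <- trimws(sub("^Name:", "", ln))
    } else if (grepl("^KEGG:", ln)) cur$kegg <- trimws(sub("^KEGG:", "", ln))
    else if (grepl("^PrecursorMZ:", ln))
      cur$mz <- as.numeric(sub("^PrecursorMZ:", "", ln))
    else if (grepl("^RT:", ln)) cur$rt <- as.numeric(sub("^RT:", "", ln))
    else if (grepl("^Adduct:", ln)) cur$adduct <- trimws(sub("^Adduct:", "", ln))
    else if (grepl("^Num Peaks:", ln)) next
    else if (grepl("^[0-9]", ln))
      peaks <- c(peaks, as.numeric(strsplit(trimws(ln), "[ \t]+")[[1]]))
  }
  flush_entry()
  structure(list(entries = do.call(rbind, entries), ms2 = ms2),
            class = "spectral_library")
}

#' @rdname csfmet-io
#' @param pathway_library a `pathway_library`.
#' @param gmt_path,edges_path output paths for the GMT set file and the
#'   tab-separated edge list (`pathway_id`, `compound_a`, `compound_b`).
#' @export
write_gmt <- function(pathway_library, gmt_path, edges_path = NULL) {
  lines <- vapply(pathway_library, function(p)
    paste(c(p$pathway_id, p$name, p$compounds), collapse = "\t"), "")
  writeLines(lines, gmt_path)
  if (!is.null(edges_path)) {
    rows <- do.call(rbind, lapply(pathway_library, function(p) {
      if (is.null(p$edges)) return(NULL)
      data.frame(pathway_id = p$pathway_id, compound_a = p$edges[, 1],
                 compound_b = p$edges[, 2], stringsAsFactors = FALSE)
    }))
    write.table(rows, edges_path, sep = "\t", row.names = FALSE,
                quote = FALSE)
  }
  invisible(gmt_path)
}

#' @rdname csfmet-io
#' @export
read_gmt <- function(gmt_path, edges_path = NULL) {
  lines <- readLines(gmt_path)
  edges_df <- if (!is.null(edges_path))
    read.csv(edges_path, sep = "\t", stringsAsFactors = FALSE) else NULL
  out <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    p <- list(pathway_id = parts[1], name = parts[2],
              compounds = parts[-(1:2)], edges = NULL)
    if (!is.null(edges_df)) {
      sub <- edges_df[edges_df$pathway_id == p$pathway_id, , drop = FALSE]
      if (nrow(sub) > 0)
        p$edges <- cbind(sub$compound_a, sub$compound_b)
    }
    p
  })
  structure(out, class = "pathway_library")
}

#' @rdname csfmet-io
#' @param truth ground-truth data.frame.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write a complete synthetic study to a directory
#'
#' Runs the whole generator and writes `samples.csv`, `features.csv`,
#' `injections.csv`, `library.msp`, `pathways.gmt`, `pathway_edges.tsv`,
#' `truth.json` and `config.json`.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @param n_pathways,pathway_size_range,pathway_universe pathway-library
#'   dimensions.
#' @return the directory path, invisibly; the generated objects as an
#'   attribute `"study"`.
#' @export
write_study <- function(config, dir, n_pathways = 10,
                        pathway_size_range = c(5, 15),
                        pathway_universe = 80) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config)
  gen <- generate_injection_table(cohort, config)
  libgen <- generate_library(gen$table, gen$truth, config)
  lib_kegg <- libgen$library$entries$kegg_id
  lib_kegg <- lib_kegg[!is.na(lib_kegg)]
  pw <- if (length(lib_kegg) >= max(pathway_size_range))
    generate_pathway_library(n_pathways, pathway_size_range,
                             seed = config$seed + 3L, compounds = lib_kegg)
  else
    generate_pathway_library(n_pathways, pathway_size_range,
                             pathway_universe, seed = config$seed + 3L)
  write_cohort(cohort, file.path(dir, "samples.csv"))
  write_injection_table(gen$table, file.path(dir, "features.csv"),
                        file.path(dir, "injections.csv"))
  write_msp(libgen$library, file.path(dir, "library.msp"))
  write_gmt(pw, file.path(dir, "pathways.gmt"),
            file.path(dir, "pathway_edges.tsv"))
  truth <- gen$truth
  truth$library_identity <- libgen$feature_identity$name[
    match(truth$feature_id, libgen$feature_identity$feature_id)]
  write_truth(truth, file.path(dir, "truth.json"))
  jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  study <- list(cohort = cohort, table = gen$table, truth = truth,
                library = libgen$library,
                feature_identity = libgen$feature_identity,
                observed_ms2 = libgen$observed_ms2, pathway_library = pw)
  invisible(structure(dir, study = study))
}
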