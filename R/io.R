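#' Write a simulated study to disk as TSV files
#'
#' Materialises a study tibble as one tab-separated file per subject-session
#' (`sub-<id>_ses-<id>_roits.tsv`, timepoints as rows, a header row of ROI
#' labels), a `manifest.csv` (subject, session, path) and, when a
#' [sim_config()] is supplied, the configuration echoed as `config.yaml`.
#'
#' @param study Tibble from [simulate_study()] (columns `subject`, `session`,
#'   `ts`).
#' @param dir Output directory; created if missing.
#' @param config Optional [sim_config()] to echo as YAML.
#' @return The manifest tibble, invisibly.
#' @export
write_study <- function(study, dir, config = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- purrr::pmap_chr(study, function(subject, session, ts) {
    path <- file.path(dir, sprintf("sub-%s_ses-%s_roits.tsv", subject, session))
    readr::write_tsv(tibble::as_tibble(ts, .name_repair = "minimal"), path, progress = FALSE)
    path
  })
  manifest <- tibble::tibble(
    subject = study$subject, session = study$session, path = paths
  )
  readr::write_csv(manifest, file.path(dir, "manifest.csv"), progress = FALSE)
  if (!is.null(config)) {
    yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))
  }
  invisible(manifest)
}

#' Read a study written by [write_study()]
#'
#' @param dir Directory containing `manifest.csv` and the per-session TSVs.
#' @return A study tibble (`subject`, `session`, `ts` list-column).
#' @export
read_study <- function(dir) {
  manifest <- readr::read_csv(
    file.path(dir, "manifest.csv"),
    col_types = readr::cols(.default = readr::col_character())
  )
  ts <- purrr::map(manifest$path, function(p) {
    as.matrix(readr::read_tsv(p, col_types = readr::cols(.default = readr::col_double()),
                              progress = FALSE))
  })
  tibble::tibble(subject = manifest$subject, session = manifest$session, ts = ts)
}

#' Write connectivity matrices as labelled TSVs
#'
#' One `sub-<id>_ses-<id>_conn.tsv` per row: an N-by-N matrix with ROI labels
#' as header row and first column.
#'
#' @param conn_tbl Tibble from [connectivity_table()].
#' @param dir Output directory; created if missing.
#' @return Paths written, invisibly.
#' @export
write_connectivity <- function(conn_tbl, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- purrr::pmap_chr(
    conn_tbl[c("subject", "session", "conn")],
    function(subject, session, conn) {
      path <- file.path(dir, sprintf("sub-%s_ses-%s_conn.tsv", subject, session))
      df <- tibble::as_tibble(conn, .name_repair = "minimal")
      df <- tibble::add_column(df, roi = rownames(conn) %||% colnames(conn), .before = 1)
      readr::write_tsv(df, path, progress = FALSE)
      path
    }
  )
  invisible(paths)
}

#' Export a thresholded network as an edge list
#'
#' @param net A `thresholded_network`.
#' @param path Output TSV path (columns `node_i`, `node_j`, `weight`).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "thresholded_network"))
  a <- net$adjacency
  idx <- which(upper.tri(a) & a != 0, arr.ind = TRUE)
  labels <- colnames(a) %||% as.character(seq_len(ncol(a)))
  el <- tibble::tibble(
    node_i = labels[idx[, 1]],
    node_j = labels[idx[, 2]],
    weight = a[idx]
  )
  el <- dplyr::arrange(el, .data$node_i, .data$node_j)
  readr::write_tsv(el, path, progress = FALSE)
  invisible(path)
}
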