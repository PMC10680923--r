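#' Neural session file I/O
#'
#' Plain-text interchange for neural sessions. Fluorescence sessions are
#' written as one CSV holding the cell and neuropil traces side by side
#' (columns `Fcell_1..n`, `Fneu_1..n`), with the morphology table in a
#' companion CSV; spike sessions as a long CSV of `cell, t_s`. A compact
#' binary container (RDS) with the same content is available for large
#' sessions via `format = "rds"`.
#'
#' @param session A [fluor_session()].
#' @param path Output path (for CSV, the morphology companion gets a
#'   `_morphology.csv` suffix).
#' @param format "csv" or "rds".
#' @return `path` invisibly (writers); the reconstructed session
#'   (readers).
#' @export
write_fluor_session <- function(session, path, format = c("csv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(session, path)
    return(invisible(path))
  }
  nc <- ncol(session$F_cell)
  df <- cbind(as.data.frame(session$F_cell),
              as.data.frame(session$F_neu))
  names(df) <- c(paste0("Fcell_", seq_len(nc)), paste0("Fneu_", seq_len(nc)))
  utils::write.csv(cbind(sample_rate = session$sample_rate, df), path,
                   row.names = FALSE)
  if (!is.null(session$morphology)) {
    utils::write.csv(session$morphology,
                     sub("\\.csv$", "_morphology.csv", path),
                     row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_fluor_session
#' @export
read_fluor_session <- function(path, format = c("csv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") return(readRDS(path))
  df <- utils::read.csv(path)
  fs <- df$sample_rate[1]
  fc <- as.matrix(df[grep("^Fcell_", names(df))])
  fn <- as.matrix(df[grep("^Fneu_", names(df))])
  morph_path <- sub("\\.csv$", "_morphology.csv", path)
  morph <- if (file.exists(morph_path)) utils::read.csv(morph_path) else NULL
  fluor_session(fc, fn, sample_rate = fs, morphology = morph)
}

#' @rdname write_fluor_session
#' @param session_e An [ephys_session()] (spike times only; raw voltages
#'   are not serialized to CSV).
#' @export
write_spike_csv <- function(session_e, path) {
  rows <- do.call(rbind, lapply(seq_along(session_e$spike_times),
                                function(j) {
    st <- session_e$spike_times[[j]]
    if (length(st) == 0) return(NULL)
    data.frame(cell = j, t_s = st)
  }))
  if (is.null(rows)) rows <- data.frame(cell = integer(0), t_s = numeric(0))
  attr(rows, "duration") <- session_e$duration
  utils::write.csv(cbind(duration_s = session_e$duration,
                         n_cells = length(session_e$spike_times), rows),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fluor_session
#' @export
read_spike_csv <- function(path) {
  df <- utils::read.csv(path)
  n_cells <- if (nrow(df)) df$n_cells[1] else 0L
  dur <- if (nrow(df)) df$duration_s[1] else 0
  st <- lapply(seq_len(n_cells), function(j) sort(df$t_s[df$cell == j]))
  ephys_session(st, duration = dur)
}

#' Kernel matrix I/O
#'
#' Long-format CSV with columns `bin`, `cell`, `beta`.
#'
#' @param K predictor x cell kernel matrix.
#' @param path CSV path.
#' @return `path` invisibly (writer); the kernel matrix (reader).
#' @export
write_kernel_csv <- function(K, path) {
  K <- as.matrix(K)
  df <- data.frame(bin = rep(seq_len(nrow(K)), ncol(K)),
                   cell = rep(seq_len(ncol(K)), each = nrow(K)),
                   beta = as.numeric(K))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kernel_csv
#' @export
read_kernel_csv <- function(path) {
  df <- utils::read.csv(path)
  K <- matrix(0, max(df$bin), max(df$cell))
  K[cbind(df$bin, df$cell)] <- df$beta
  K
}
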