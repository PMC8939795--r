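# text serialization: CSV for tabular payloads, JSON sidecars for provenance

fnv1a <- function(x) {
  s <- paste(utils::capture.output(utils::str(x)), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    # xor on the low 16 bits only (byte values < 256); keeps h in double range
    h <- (h %/% 65536) * 65536 + bitwXor(h %% 65536, b %% 65536)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write/read a time-series set as CSV
#'
#' Long-format CSV (`time`, one column per channel) plus a `.json` sidecar
#' carrying sampling rate, labels and provenance (seed, config hash).
#'
#' @param ts a [ts_set()] object.
#' @param path CSV path; the sidecar is written at `paste0(path, ".json")`.
#' @return `write_ts_csv` returns `path` invisibly; `read_ts_csv` a
#'   [ts_set()].
#' @export
write_ts_csv <- function(ts, path) {
  df <- data.frame(time = seq_len(ncol(ts$data)) / ts$fs,
                   t(ts$data), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(fs = ts$fs, labels = ts$labels, meta = ts$meta,
               config_hash = fnv1a(ts$meta),
               package_version = as.character(utils::packageVersion("cbgtstim")))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ts_csv
#' @export
read_ts_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  labels <- setdiff(colnames(df), "time")
  ts_set(t(as.matrix(df[, labels, drop = FALSE])), labels, side$fs,
         meta = side$meta)
}

#' Write/read a feature set as flat CSV
#'
#' Long format with columns `freq`, `channel` (source or "from->to" pair),
#' `feature` (`psd`, `npd_forward`, `npd_reverse`, `npd_zero_lag`) and
#' `value`; the format used for ABC fitting targets.
#'
#' @param features a [feature_set()] object.
#' @param path CSV path.
#' @return `write_feature_csv` returns `path` invisibly; `read_feature_csv`
#'   a `cbgt_features` object.
#' @export
write_feature_csv <- function(features, path) {
  rows <- list()
  for (ch in colnames(features$psd))
    rows[[length(rows) + 1L]] <- data.frame(freq = features$freqs,
                                            channel = ch, feature = "psd",
                                            value = features$psd[, ch])
  for (pr in names(features$npd))
    for (comp in names(features$npd[[pr]]))
      rows[[length(rows) + 1L]] <- data.frame(
        freq = features$freqs, channel = pr,
        feature = paste0("npd_", comp), value = features$npd[[pr]][[comp]])
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  freqs <- sort(unique(df$freq))
  chans <- unique(df$channel[df$feature == "psd"])
  psd <- vapply(chans, function(ch) {
    sub <- df[df$feature == "psd" & df$channel == ch, ]
    sub$value[order(sub$freq)]
  }, numeric(length(freqs)))
  colnames(psd) <- chans
  npd <- list()
  for (pr in unique(df$channel[startsWith(df$feature, "npd_")])) {
    npd[[pr]] <- lapply(c(forward = "npd_forward", reverse = "npd_reverse",
                          zero_lag = "npd_zero_lag"), function(ft) {
      sub <- df[df$feature == ft & df$channel == pr, ]
      sub$value[order(sub$freq)]
    })
  }
  structure(list(freqs = freqs, psd = psd, npd = npd,
                 meta = list(source = path)),
            class = "cbgt_features")
}

#' Write a provenance sidecar
#'
#' JSON record of the configuration hash, seed and package version written
#' next to every CLI output.
#'
#' @param path output file the sidecar describes.
#' @param config the configuration object in force.
#' @param seed integer seed.
#' @return Sidecar path, invisibly.
#' @export
write_provenance <- function(path, config, seed) {
  side <- list(output = basename(path), seed = seed,
               config_hash = fnv1a(config),
               package_version = as.character(utils::packageVersion("cbgtstim")),
               written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  out <- paste0(path, ".provenance.json")
  jsonlite::write_json(side, out, auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}
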