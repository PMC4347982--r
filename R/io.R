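# Plain-text persistence: spike rasters in the columnar gdf convention
# (neuron_id <TAB> spike_time_ms), weight matrices as TSV with a JSON
# metadata sidecar, and flat key=value configuration files.

#' Write a spike raster as columnar text (gdf convention)
#'
#' One line per spike: `neuron_id<TAB>spike_time_ms`, times at bin
#' resolution.
#'
#' @param raster A `spike_raster`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gdf <- function(raster, path) {
  m <- unclass(raster)
  idx <- which(m == 1, arr.ind = TRUE)
  t0 <- attr(raster, "t0"); db <- attr(raster, "dt_bin")
  df <- data.frame(neuron = idx[, 1],
                   time = t0 + (idx[, 2] - 1) * db)
  df <- df[order(df$time, df$neuron), ]
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read columnar spike text back into a raster
#'
#' @param path File written by [write_gdf()] (or any two-column
#'   neuron/time text).
#' @param n_neurons Number of neurons (rows) of the raster.
#' @param n_bins Number of bins; inferred from the last spike when `NULL`.
#' @param dt_bin Bin width (ms).
#' @param t0 Start time of the first bin (ms).
#' @return A `spike_raster`.
#' @export
read_gdf <- function(path, n_neurons, n_bins = NULL, dt_bin = 1, t0 = 0) {
  df <- utils::read.table(path, sep = "\t",
                          col.names = c("neuron", "time"))
  bins <- floor((df$time - t0) / dt_bin) + 1L
  if (is.null(n_bins)) n_bins <- if (nrow(df)) max(bins) else 0L
  m <- matrix(0L, n_neurons, n_bins)
  if (nrow(df)) m[cbind(df$neuron, bins)] <- 1L
  spike_raster(m, dt_bin = dt_bin, t0 = t0)
}

#' Write RBM couplings as TSV matrices plus a JSON sidecar
#'
#' @param W An [rbm_weights()] object.
#' @param prefix Path prefix; writes `<prefix>_w_sh.tsv`, `<prefix>_w_ah.tsv`
#'   (plus `_w_mo` / `_w_mm` when present) and `<prefix>_meta.json`.
#' @param meta Optional named list merged into the sidecar.
#' @return `prefix`, invisibly.
#' @export
write_weights <- function(W, prefix, meta = list()) {
  blocks <- list(w_sh = W$w_sh, w_ah = W$w_ah, w_mo = W$w_mo, w_mm = W$w_mm)
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  for (nm in names(blocks))
    utils::write.table(blocks[[nm]], paste0(prefix, "_", nm, ".tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  side <- c(list(blocks = names(blocks),
                 dims = lapply(blocks, dim)), meta)
  jsonlite::write_json(side, paste0(prefix, "_meta.json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' Read couplings written by [write_weights()]
#'
#' @param prefix Path prefix used when writing.
#' @return An [rbm_weights()] object with the sidecar attached as attribute
#'   `meta`.
#' @export
read_weights <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  blocks <- lapply(meta$blocks, function(nm)
    as.matrix(utils::read.table(paste0(prefix, "_", nm, ".tsv"), sep = "\t")))
  names(blocks) <- meta$blocks
  W <- rbm_weights(blocks$w_sh, blocks$w_ah,
                   w_mo = blocks$w_mo, w_mm = blocks$w_mm)
  attr(W, "meta") <- meta
  W
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment.
#' Values are parsed as numbers or logicals where possible. The result can be
#' spliced into [agent_config()] via `do.call`.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "[=:]", fixed = FALSE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = ":"))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
      else if (toupper(val) %in% c("TRUE", "FALSE")) as.logical(toupper(val))
      else val
  }
  out
}

#' Write a flat key=value configuration file
#'
#' @param config Named list of scalar values.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  writeLines(vapply(names(config), function(k)
    paste0(k, " = ", format(config[[k]])), character(1)), path)
  invisible(path)
}
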