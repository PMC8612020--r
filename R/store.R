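# Keyed signal store: one file per sample holding every signal the
# pipeline produces under hierarchical string keys
# "<signal>/<chrom>/<binsize>/<flags>". 100-bp base-resolution signals are
# stored once; anything rebinned or corrected is reproducible from them
# plus parameters. Backed by R native serialization; round trips are
# bit-identical.

store_key <- function(signal, chrom = NULL, bin_size = NULL, flags = NULL) {
  parts <- c(signal, chrom, if (!is.null(bin_size)) as.character(bin_size),
             flags)
  paste(parts, collapse = "/")
}

#' Open (or create) a keyed signal store
#'
#' @param path store file; created empty if absent.
#' @param metadata optional named list recorded on creation (assembly
#'   name, parameters, tool version).
#' @return a `keyed_store` handle.
#' @export
open_store <- function(path, metadata = NULL) {
  env <- new.env(parent = emptyenv())
  if (file.exists(path)) {
    dat <- readRDS(path)
    for (k in names(dat$data)) assign(k, dat$data[[k]], envir = env)
    metadata <- dat$metadata
  } else {
    if (is.null(metadata)) metadata <- list()
    metadata$created <- format(Sys.time())
    metadata$tool <- paste("rdcnv",
                           as.character(utils::packageVersion("rdcnv")))
  }
  structure(list(path = path, env = env, metadata = metadata),
            class = "keyed_store")
}

store_flush <- function(store) {
  keys <- ls(store$env, sorted = TRUE)
  dat <- list(metadata = store$metadata,
              data = setNames(lapply(keys, get, envir = store$env), keys))
  saveRDS(dat, store$path)
  invisible(store)
}

#' Write a signal (or any object) under a hierarchical key
#'
#' @param store a `keyed_store`.
#' @param signal signal name (e.g. "rd", "rd_corrected", "q0", "gc",
#'   "calls", "snp_likelihood").
#' @param value numeric array or record table.
#' @param chrom,bin_size,flags optional key components.
#' @return the store, invisibly. Every write is persisted and logged
#'   (message with key and length/dimension).
#' @export
put_signal <- function(store, signal, value, chrom = NULL, bin_size = NULL,
                       flags = NULL) {
  key <- store_key(signal, chrom, bin_size, flags)
  assign(key, value, envir = store$env)
  shape <- if (is.data.frame(value)) paste(dim(value), collapse = "x")
           else as.character(length(value))
  message("store: wrote ", key, " [", shape, "]")
  store_flush(store)
}

#' Read a signal back from the store
#'
#' A missing key errors, naming the nearest existing keys.
#'
#' @inheritParams put_signal
#' @return the stored object, bit-identical to what was written.
#' @export
get_signal <- function(store, signal, chrom = NULL, bin_size = NULL,
                       flags = NULL) {
  key <- store_key(signal, chrom, bin_size, flags)
  if (!exists(key, envir = store$env, inherits = FALSE)) {
    keys <- ls(store$env)
    near <- keys[startsWith(keys, strsplit(key, "/")[[1]][1])]
    if (length(near) == 0L)
      near <- utils::head(keys[order(utils::adist(keys, key))], 3L)
    stop("no such key: ", key,
         if (length(near)) paste0(" (nearest: ",
                                  paste(near, collapse = ", "), ")"))
  }
  get(key, envir = store$env, inherits = FALSE)
}

#' List stored keys
#' @param store a `keyed_store`.
#' @return character vector of keys, sorted.
#' @export
list_signals <- function(store) ls(store$env, sorted = TRUE)

#' Delete a key (e.g. a derived signal, to be recomputed from base data)
#' @inheritParams put_signal
#' @export
delete_signal <- function(store, signal, chrom = NULL, bin_size = NULL,
                          flags = NULL) {
  key <- store_key(signal, chrom, bin_size, flags)
  if (exists(key, envir = store$env, inherits = FALSE))
    rm(list = key, envir = store$env)
  store_flush(store)
}

#' @export
print.keyed_store <- function(x, ...) {
  cat("keyed_store:", x$path, "-", length(ls(x$env)), "key(s)\n")
  invisible(x)
}

# Store a whole binned_track / retrieve one, one key per chromosome.
put_track <- function(store, signal, track, flags = NULL) {
  for (ch in names(track$values))
    put_signal(store, signal, track$values[[ch]], chrom = ch,
               bin_size = track$bin_size, flags = flags)
  put_signal(store, paste0(signal, "_lengths"), track$lengths,
             bin_size = track$bin_size, flags = flags)
}

get_track <- function(store, signal, bin_size, flags = NULL) {
  lengths <- get_signal(store, paste0(signal, "_lengths"),
                        bin_size = bin_size, flags = flags)
  vals <- lapply(names(lengths), function(ch)
    get_signal(store, signal, chrom = ch, bin_size = bin_size,
               flags = flags))
  names(vals) <- names(lengths)
  binned_track(bin_size, vals, lengths)
}
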