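# Map/collate/reduce machinery over hash-partitioned key/value stores.
#
# The object model mirrors classic MPI-style MapReduce libraries: a KV store
# holds key/value pairs spread over logical partitions ("workers"), collate()
# groups values by key into a KMV store, reduce() turns KMV pairs back into KV
# pairs.  Partitions larger than `pagesize` bytes are paged out to spill files
# and read back transparently; the logical content of a store never depends on
# n_workers or pagesize.

#' Engine configuration
#'
#' Bundles the knobs shared by all map/collate/reduce operations: the number of
#' logical partitions ("workers"), the per-partition memory budget in bytes
#' above which pages spill to disk, and where spill files live.
#'
#' Workers are logical: partitions are processed sequentially in partition
#' order, which makes results reproducible while preserving the per-partition
#' output contract a concurrent backend would have to honour.
#'
#' @param n_workers number of logical partitions (>= 1). Default 1.
#' @param pagesize per-partition in-memory budget in bytes (> 0) before pages
#'   spill to `spill_dir`. Default 1 GiB, i.e. effectively in-memory at desk
#'   scale.
#' @param spill_dir directory for spill files; created on demand.
#' @param keep_temp keep spill files after a store is garbage-replaced
#'   (for debugging); default FALSE.
#' @return an object of class `engine_config`.
#' @examples
#' cfg <- engine_config(n_workers = 4, pagesize = 2^16)
#' @export
engine_config <- function(n_workers = 1L, pagesize = 2^30, spill_dir = NULL,
                          keep_temp = FALSE) {
  n_workers <- as.integer(n_workers)
  if (is.na(n_workers) || n_workers < 1L) stop("n_workers must be >= 1")
  if (!is.numeric(pagesize) || pagesize <= 0) stop("pagesize must be > 0")
  if (is.null(spill_dir)) spill_dir <- file.path(tempdir(), "zoneworm-spill")
  cfg <- list(n_workers = n_workers, pagesize = as.numeric(pagesize),
              spill_dir = spill_dir, keep_temp = isTRUE(keep_temp),
              counters = new.env(parent = emptyenv()))
  cfg$counters$pairs_emitted <- 0
  cfg$counters$bytes_spilled <- 0
  cfg$counters$pages_written <- 0
  class(cfg) <- "engine_config"
  cfg
}

#' Engine counters
#'
#' Cumulative I/O and emission counters for an [engine_config()]: total pairs
#' emitted by map/reduce callbacks, bytes spilled to disk, and spill pages
#' written.
#'
#' @param config an `engine_config`.
#' @return named numeric vector.
#' @export
engine_counters <- function(config) {
  c(pairs_emitted = config$counters$pairs_emitted,
    bytes_spilled = config$counters$bytes_spilled,
    pages_written = config$counters$pages_written)
}

# 32-bit FNV-1a over the UTF-8 bytes of each key, vectorized over keys.
# offset basis 2166136261 (0x811C9DC5), prime 16777619 (0x01000193).
# 32-bit modular multiplication is done in 16-bit halves so every intermediate
# stays exactly representable in a double.
fnv1a32 <- function(keys) {
  n <- length(keys)
  if (n == 0L) return(numeric(0))
  lens <- nchar(keys, type = "bytes")
  if (any(lens == 0L)) stop("keys must be non-empty byte-strings")
  maxlen <- max(lens)
  if (length(unique(lens)) == 1L) {
    bytes <- matrix(utf8ToInt(paste(keys, collapse = "")), nrow = maxlen)
    if (any(bytes > 255L)) bytes <- .fnv_bytes_pad(keys, maxlen)  # non-ASCII
  } else {
    bytes <- .fnv_bytes_pad(keys, maxlen)
  }
  hi <- rep(33052, n)   # 0x811C
  lo <- rep(40389, n)   # 0x9DC5
  for (i in seq_len(maxlen)) {
    b <- bytes[i, ]
    live <- !is.na(b)
    lo[live] <- bitwXor(as.integer(lo[live]), as.integer(b[live]))
    t0 <- lo[live] * 16777619
    u <- (hi[live] * 16777619) %% 65536
    h <- (u * 65536 + t0) %% 4294967296
    hi[live] <- h %/% 65536
    lo[live] <- h %% 65536
  }
  hi * 65536 + lo
}

# fallback byte extraction: per-key utf8ToInt, NA-padded to a common length.
.fnv_bytes_pad <- function(keys, maxlen) {
  vapply(keys, function(k) {
    b <- utf8ToInt(k)
    # encode multi-byte characters as their UTF-8 bytes
    if (any(b > 255L)) b <- as.integer(charToRaw(k))
    length(b) <- maxlen
    b
  }, integer(maxlen), USE.NAMES = FALSE)
}

#' Partition owner of a key
#'
#' Maps each key to the logical partition that owns it: the FNV-1a 32-bit hash
#' of the key's bytes, modulo the number of workers.  The hash is fixed and
#' seed-independent, so ownership is stable across runs and platforms.
#'
#' @param keys character vector of non-empty keys.
#' @param n_workers number of partitions (>= 1).
#' @return integer vector of 0-based partition indices, same length as `keys`.
#' @examples
#' partition_owner(c("ACGTA", "ACGTA", "TTTTT"), 8)
#' @export
partition_owner <- function(keys, n_workers) {
  n_workers <- as.integer(n_workers)
  if (is.na(n_workers) || n_workers < 1L) stop("n_workers must be >= 1")
  if (n_workers == 1L) return(rep(0L, length(keys)))
  as.integer(fnv1a32(keys) %% n_workers)
}

# ---- store internals ---------------------------------------------------------

# A kv_store is a list:
#   parts: list of partitions, each list(key=chr, value=chr, files=chr)
#          `files` are spill pages (RDS of list(key, value)), oldest first;
#          the key/value vectors are the resident (most recent) page.
#   n_workers, pagesize, spill_dir
# A kmv_store is identical except partitions hold (key=chr, values=list) and
# spill pages hold list(key, values).

.store_bytes <- function(key, value_or_values) {
  if (is.list(value_or_values)) {
    vb <- sum(nchar(unlist(value_or_values, use.names = FALSE), type = "bytes"))
    nv <- length(unlist(value_or_values, use.names = FALSE))
  } else {
    vb <- sum(nchar(value_or_values, type = "bytes"))
    nv <- length(value_or_values)
  }
  sum(nchar(key, type = "bytes")) + vb + 16 * (length(key) + nv)
}

.spill_page <- function(page, config) {
  if (!dir.exists(config$spill_dir))
    dir.create(config$spill_dir, recursive = TRUE)
  path <- tempfile("page-", tmpdir = config$spill_dir, fileext = ".spill")
  ok <- try(saveRDS(page, path, compress = FALSE), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write spill page: ", path)
  config$counters$pages_written <- config$counters$pages_written + 1
  config$counters$bytes_spilled <- config$counters$bytes_spilled +
    .store_bytes(page[[1L]], page[[2L]])
  path
}

.read_page <- function(path) {
  if (!file.exists(path)) stop("missing spill page: ", path)
  readRDS(path)
}

# Cut (key, value) vectors into pages no larger than pagesize; spill all but
# the last page. Returns a partition record.
.make_partition_kv <- function(key, value, config) {
  files <- character(0)
  total <- .store_bytes(key, value)
  if (total > config$pagesize && length(key) > 1L) {
    per <- cumsum(nchar(key, type = "bytes") + nchar(value, type = "bytes") + 32)
    page_id <- pmin(per %/% config$pagesize, .Machine$integer.max)
    last <- page_id[length(page_id)]
    if (last > 0) {
      for (p in unique(page_id[page_id < last])) {
        sel <- page_id == p
        files <- c(files, .spill_page(list(key = key[sel], value = value[sel]),
                                      config))
      }
      keep <- page_id == last
      key <- key[keep]; value <- value[keep]
    }
  }
  list(key = key, value = value, files = files)
}

.make_partition_kmv <- function(key, values, config) {
  files <- character(0)
  total <- .store_bytes(key, values)
  if (total > config$pagesize && length(key) > 1L) {
    per <- cumsum(nchar(key, type = "bytes") +
                    vapply(values, function(v) sum(nchar(v, type = "bytes")) +
                             16 * length(v), 0) + 32)
    page_id <- per %/% config$pagesize
    last <- page_id[length(page_id)]
    if (last > 0) {
      for (p in unique(page_id[page_id < last])) {
        sel <- page_id == p
        files <- c(files,
                   .spill_page(list(key = key[sel], values = values[sel]),
                               config))
      }
      keep <- page_id == last
      key <- key[keep]; values <- values[keep]
    }
  }
  list(key = key, values = values, files = files)
}

# Build a kv_store from flat emission vectors.
.build_kv_store <- function(key, value, config) {
  if (is.null(key)) key <- character(0)
  if (is.null(value)) value <- character(0)
  stopifnot(length(key) == length(value))
  if (length(key) && any(!nzchar(key)))
    stop("emitted keys must be non-empty")
  config$counters$pairs_emitted <- config$counters$pairs_emitted + length(key)
  owner <- partition_owner(key, config$n_workers)
  parts <- vector("list", config$n_workers)
  for (w in seq_len(config$n_workers) - 1L) {
    sel <- owner == w
    parts[[w + 1L]] <- .make_partition_kv(key[sel], value[sel], config)
  }
  structure(list(parts = parts, n_workers = config$n_workers,
                 pagesize = config$pagesize, spill_dir = config$spill_dir),
            class = "kv_store")
}

# Materialize one partition (spilled pages first, resident page last).
.partition_kv_pairs <- function(part) {
  if (length(part$files)) {
    pages <- lapply(part$files, .read_page)
    key <- c(unlist(lapply(pages, `[[`, "key"), use.names = FALSE), part$key)
    value <- c(unlist(lapply(pages, `[[`, "value"), use.names = FALSE),
               part$value)
    list(key = key, value = value)
  } else {
    list(key = part$key, value = part$value)
  }
}

.partition_kmv_pairs <- function(part) {
  if (length(part$files)) {
    pages <- lapply(part$files, .read_page)
    key <- c(unlist(lapply(pages, `[[`, "key"), use.names = FALSE), part$key)
    values <- c(do.call(c, lapply(pages, `[[`, "values")), part$values)
    list(key = key, values = values)
  } else {
    list(key = part$key, values = part$values)
  }
}

#' All pairs of a KV store
#'
#' Materializes the full logical content of a KV store (resident pages plus any
#' spilled pages) as a data frame, in partition order.
#'
#' @param store a `kv_store`.
#' @return data.frame with columns `key`, `value` (character).
#' @export
kv_pairs <- function(store) {
  stopifnot(inherits(store, "kv_store"))
  got <- lapply(store$parts, .partition_kv_pairs)
  k <- unlist(lapply(got, `[[`, "key"), use.names = FALSE)
  v <- unlist(lapply(got, `[[`, "value"), use.names = FALSE)
  data.frame(key = if (is.null(k)) character(0) else k,
             value = if (is.null(v)) character(0) else v,
             stringsAsFactors = FALSE)
}

#' All pairs of a KMV store
#'
#' @param store a `kmv_store`.
#' @return list with `key` (character, globally unique) and `values`
#'   (list of character vectors), in partition order.
#' @export
kmv_pairs <- function(store) {
  stopifnot(inherits(store, "kmv_store"))
  got <- lapply(store$parts, .partition_kmv_pairs)
  list(key = unlist(lapply(got, `[[`, "key"), use.names = FALSE),
       values = do.call(c, c(lapply(got, `[[`, "values"), list(list()))))
}

#' @export
print.kv_store <- function(x, ...) {
  np <- vapply(x$parts, function(p) length(p$key), 0L)
  sp <- vapply(x$parts, function(p) length(p$files), 0L)
  cat("<kv_store> ", x$n_workers, " partition(s), ",
      sum(np), " resident pair(s), ", sum(sp), " spilled page(s)\n", sep = "")
  invisible(x)
}

#' @export
print.kmv_store <- function(x, ...) {
  np <- vapply(x$parts, function(p) length(p$key), 0L)
  cat("<kmv_store> ", x$n_workers, " partition(s), ",
      sum(np), " resident key(s)\n", sep = "")
  invisible(x)
}

# ---- map / collate / reduce --------------------------------------------------

#' Map: emit key/value pairs from items or from an existing store
#'
#' Applies `map_fn` to every item of `items` (a list or vector), or to every
#' key/value pair when `items` is a `kv_store`.  The callback returns `NULL`
#' (emit nothing) or a list with character vectors `key` and `value` of equal
#' length (a scalar `value` is recycled), so a single call may emit many pairs.
#' Emitted pairs are routed to the partition given by [partition_owner()];
#' partitions over `pagesize` spill excess pages to disk.
#'
#' @param items list/vector of input items, or a `kv_store`.
#' @param map_fn callback: `function(item)` for sequence input,
#'   `function(key, value)` for store input.
#' @param config an [engine_config()].
#' @return a `kv_store`.
#' @examples
#' cfg <- engine_config()
#' kv <- mr_map(list("ACGTA"), function(s) list(key = s, value = "1"), cfg)
#' kv_pairs(kv)
#' @export
mr_map <- function(items, map_fn, config = engine_config()) {
  emit_k <- list(); emit_v <- list(); j <- 0L
  add <- function(res, what) {
    if (is.null(res)) return(invisible())
    if (!is.list(res) || is.null(res$key))
      stop("map_fn must return NULL or list(key=, value=) (", what, ")")
    k <- as.character(res$key)
    if (!length(k)) return(invisible())
    v <- as.character(if (is.null(res$value)) "" else res$value)
    if (length(v) == 1L && length(k) > 1L) v <- rep(v, length(k))
    if (length(v) != length(k))
      stop("map_fn emitted ", length(k), " keys but ", length(v),
           " values (", what, ")")
    j <<- j + 1L
    emit_k[[j]] <<- k
    emit_v[[j]] <<- v
    invisible()
  }
  if (inherits(items, "kv_store")) {
    pairs <- kv_pairs(items)
    for (i in seq_len(nrow(pairs))) {
      res <- tryCatch(map_fn(pairs$key[i], pairs$value[i]), error = function(e)
        stop("map_fn failed on pair with key '", pairs$key[i], "': ",
             conditionMessage(e), call. = FALSE))
      add(res, paste0("key ", pairs$key[i]))
    }
  } else {
    for (i in seq_along(items)) {
      res <- tryCatch(map_fn(items[[i]]), error = function(e)
        stop("map_fn failed on item ", i, ": ", conditionMessage(e),
             call. = FALSE))
      add(res, paste0("item ", i))
    }
  }
  .build_kv_store(unlist(emit_k, use.names = FALSE),
                  unlist(emit_v, use.names = FALSE), config)
}

#' Collate: group values by key
#'
#' Extracts the distinct keys of a KV store and gathers all values associated
#' with each key into one key/multivalue pair.  Because every pair of a key
#' already lives on the key's owner partition, grouping is performed partition
#' by partition (spilled pages are read back first), and each distinct key ends
#' up on exactly one partition.  Keys are sorted within a partition; the order
#' of values within a key is unspecified and downstream reducers must not
#' depend on it.
#'
#' @param kv a `kv_store`.
#' @param config an [engine_config()].
#' @return a `kmv_store`.
#' @export
mr_collate <- function(kv, config = engine_config()) {
  stopifnot(inherits(kv, "kv_store"))
  parts <- vector("list", kv$n_workers)
  for (w in seq_along(kv$parts)) {
    got <- tryCatch(.partition_kv_pairs(kv$parts[[w]]), error = function(e)
      stop("collate: ", conditionMessage(e), call. = FALSE))
    if (length(got$key)) {
      grp <- split(got$value, got$key)           # sorted unique keys
      parts[[w]] <- .make_partition_kmv(names(grp), unname(grp), config)
    } else {
      parts[[w]] <- list(key = character(0), values = list(),
                         files = character(0))
    }
  }
  structure(list(parts = parts, n_workers = kv$n_workers,
                 pagesize = config$pagesize, spill_dir = config$spill_dir),
            class = "kmv_store")
}

#' Reduce: emit key/value pairs from each key/multivalue pair
#'
#' Processes every KMV pair exactly once.  With `vectorized = FALSE` the
#' callback is `function(key, values)` returning `NULL` or
#' `list(key=, value=)`; with `vectorized = TRUE` it is
#' `function(keys, values_list)` called once per partition page, which is much
#' faster for large stores.  Emitted pairs are hash-routed into a fresh KV
#' store.
#'
#' @param kmv a `kmv_store`.
#' @param reduce_fn the callback.
#' @param config an [engine_config()].
#' @param vectorized call the reducer once per page over all keys at once.
#' @return a `kv_store`.
#' @export
mr_reduce <- function(kmv, reduce_fn, config = engine_config(),
                      vectorized = FALSE) {
  stopifnot(inherits(kmv, "kmv_store"))
  emit_k <- list(); emit_v <- list(); j <- 0L
  take <- function(res) {
    if (is.null(res)) return(invisible())
    k <- as.character(res$key)
    if (!length(k)) return(invisible())
    v <- as.character(res$value)
    if (length(v) == 1L && length(k) > 1L) v <- rep(v, length(k))
    if (length(v) != length(k)) stop("reduce_fn key/value length mismatch")
    j <<- j + 1L; emit_k[[j]] <<- k; emit_v[[j]] <<- v
    invisible()
  }
  for (w in seq_along(kmv$parts)) {
    got <- .partition_kmv_pairs(kmv$parts[[w]])
    if (!length(got$key)) next
    if (vectorized) {
      take(reduce_fn(got$key, got$values))
    } else {
      for (i in seq_along(got$key)) {
        res <- tryCatch(reduce_fn(got$key[i], got$values[[i]]),
                        error = function(e)
          stop("reduce_fn failed on key '", got$key[i], "': ",
               conditionMessage(e), call. = FALSE))
        take(res)
      }
    }
  }
  .build_kv_store(unlist(emit_k, use.names = FALSE),
                  unlist(emit_v, use.names = FALSE), config)
}

# Remove spill files accumulated under a config's spill_dir.
.clean_spill <- function(config) {
  if (config$keep_temp) return(invisible())
  if (dir.exists(config$spill_dir))
    unlink(list.files(config$spill_dir, pattern = "\\.spill$",
                      full.names = TRUE))
  invisible()
}
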