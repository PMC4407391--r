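# Genome-wide genotypes are packed, per (sample, experiment, chromosome),
# into fixed-capacity blocks of B consecutive markers; a per-layout index
# maps each marker to its (chromosome, block, offset) slot.  The payload is
# a character string of 2 characters per slot (the two allele codes), so a
# B = 500 block is a 1000-character string and "00" is a missing slot.

#' Allocate a block layout for per-chromosome marker counts
#'
#' Each chromosome with `m` markers occupies `ceiling(m / block_size)`
#' blocks; space is always reserved for full blocks, so the trailing block
#' of a chromosome carries `0/0` padding slots.  The default block size of
#' 500 genotypes per record is the package's operating point: load cost is
#' essentially flat for larger blocks while wasted padding grows.
#'
#' @param marker_counts named integer vector, chromosome -> marker count.
#' @param block_size genotypes per block (positive integer).
#' @return An object of class `block_layout` with elements `block_size`,
#'   `markers`, `blocks` (per-chromosome block counts), `total_blocks` and
#'   `total_slots`.
#' @examples
#' allocate_layout(c(`1` = 2500), 500)$blocks   # 5
#' allocate_layout(c(`1` = 2501), 500)$blocks   # 6
#' @export
allocate_layout <- function(marker_counts, block_size = 500L) {
  block_size <- as.integer(block_size)
  if (is.na(block_size) || block_size < 1L) {
    stop("block_size must be a positive integer")
  }
  counts <- as.integer(marker_counts)
  if (any(is.na(counts) | counts < 0L)) {
    stop("marker counts must be non-negative integers")
  }
  names(counts) <- names(marker_counts)
  blocks <- as.integer(ceiling(counts / block_size))
  structure(list(block_size = block_size, markers = counts,
                 blocks = blocks,
                 total_blocks = sum(blocks),
                 total_slots = sum(blocks) * block_size),
            class = "block_layout")
}

#' @export
print.block_layout <- function(x, ...) {
  cat(sprintf("<block layout> B=%d | %d markers | %d blocks (%d slots)\n",
              x$block_size, sum(x$markers), x$total_blocks, x$total_slots))
  invisible(x)
}

#' Encode and decode block payloads
#'
#' `encode_payload()` packs a vector of normalized calls (in slot order,
#' one chromosome) into block payload strings, padding the trailing block
#' with `"00"` slots; `decode_payload()` is its inverse.  The round trip is
#' exact for any calls over the allele alphabet.
#'
#' @param calls character vector of normalized calls (`"A/C"`, `"0/0"`, ...).
#' @param block_size genotypes per block.
#' @param payloads character vector of payload strings.
#' @param n optional number of leading slots to return (drops the padding);
#'   default returns all slots.
#' @return `encode_payload()`: character vector of payload strings (each
#'   `2 * block_size` characters); `decode_payload()`: character vector of
#'   calls.
#' @export
encode_payload <- function(calls, block_size = 500L) {
  block_size <- as.integer(block_size)
  m <- length(calls)
  nblock <- ceiling(m / block_size)
  if (nblock == 0L) return(character(0))
  codes <- rep("00", nblock * block_size)
  if (m) codes[seq_len(m)] <- gsub("/", "", calls, fixed = TRUE)
  if (any(nchar(codes) != 2L)) stop("calls must be two single allele codes")
  big <- paste(codes, collapse = "")
  starts <- (seq_len(nblock) - 1L) * 2L * block_size + 1L
  substring(big, starts, starts + 2L * block_size - 1L)
}

#' @rdname encode_payload
#' @export
decode_payload <- function(payloads, n = NULL) {
  if (!length(payloads)) return(character(0))
  big <- paste(payloads, collapse = "")
  nslots <- nchar(big) / 2L
  starts <- (seq_len(nslots) - 1L) * 2L + 1L
  a1 <- substring(big, starts, starts)
  a2 <- substring(big, starts + 1L, starts + 1L)
  out <- normalize_call(a1, a2)
  if (!is.null(n)) out <- out[seq_len(n)]
  out
}

# Build (or reuse) the marker->slot index of a named layout from a marker
# map (marker_id, chromosome, bp).  Markers are ordered by (chromosome, bp)
# and assigned consecutive slots; an existing layout of the same name is
# reused if it indexes an identical marker set (several experiments run on
# the same chip share one index), otherwise the call errors.
gv_make_layout <- function(db, layout, map_ids, chromosome, bp,
                           block_size = 500L) {
  block_size <- as.integer(block_size)
  lt <- db$tables$layouts
  existing <- match(layout, lt$layout)
  snp <- db$tables$snpblocks
  if (!is.na(existing)) {
    have <- snp[snp$layout == layout, , drop = FALSE]
    if (lt$block_size[existing] != block_size ||
        !setequal(have$marker_id, map_ids)) {
      stop("layout '", layout, "' already exists with a different ",
           "marker set or block size")
    }
    return(invisible(layout))
  }
  ord <- order(chromosome, bp, map_ids)
  chr <- chromosome[ord]
  rank0 <- sequence(rle(chr)$lengths) - 1L   # 0-based rank within chromosome
  gv_insert(db, "layouts",
            data.frame(layout = layout, block_size = block_size))
  gv_insert(db, "snpblocks", data.frame(
    layout = layout, marker_id = map_ids[ord], chromosome = chr,
    block_index = rank0 %/% block_size, offset = rank0 %% block_size))
  invisible(layout)
}

# Slot geometry of a stored layout: snpblocks rows plus a flat slot position
# (1-based across chromosomes, full blocks contiguous) used by the bulk
# encoder, and per-(chromosome, block) payload start offsets.
gv_layout_geometry <- function(db, layout) {
  lt <- db$tables$layouts
  i <- match(layout, lt$layout)
  if (is.na(i)) stop("unknown layout: ", layout)
  B <- lt$block_size[i]
  snp <- db$tables$snpblocks
  snp <- snp[snp$layout == layout, , drop = FALSE]
  blocks <- unique(snp[, c("chromosome", "block_index")])
  blocks <- blocks[order(blocks$chromosome, blocks$block_index), ,
                   drop = FALSE]
  bkey <- paste(blocks$chromosome, blocks$block_index)
  base <- (match(paste(snp$chromosome, snp$block_index), bkey) - 1L) * B
  list(block_size = B, snp = snp, blocks = blocks,
       slot = base + snp$offset + 1L,
       total_slots = nrow(blocks) * B)
}

#' Locate a marker's storage slot
#'
#' Returns the chromosome, 0-based block index and 0-based offset under
#' which the marker's genotypes are stored in the named layout.  The
#' storage chromosome is the chromosome **at load time**: if a later map
#' build moves the marker, its blocks stay where they were written, and
#' selection by current-build position still finds them through this index.
#'
#' @param db a `gdb` object.
#' @param marker marker name (aliases allowed).
#' @param layout layout name.
#' @return A list with `chromosome`, `block_index`, `offset`, or `NULL` if
#'   the marker is not indexed in this layout (callers may then fall back
#'   to the row store).
#' @export
gdb_locate <- function(db, marker, layout) {
  id <- resolve_marker(db, marker)
  snp <- db$tables$snpblocks
  i <- which(snp$layout == layout & snp$marker_id == id)
  if (!length(i)) return(NULL)
  list(chromosome = snp$chromosome[i[1L]],
       block_index = snp$block_index[i[1L]],
       offset = snp$offset[i[1L]])
}

# Encode one sample's calls into genotypeblocks rows (no insertion).
# `calls` is a character vector of normalized calls named by marker_id, or
# aligned with the geometry's snp rows via `ids`.
gv_encode_sample_rows <- function(geom, ids, calls, sample_id,
                                  experiment_id, layout) {
  pos <- geom$slot[match(ids, geom$snp$marker_id)]
  if (anyNA(pos)) {
    stop("call(s) for marker(s) not indexed in layout '", layout,
         "'; load the marker map first")
  }
  slots <- rep("00", geom$total_slots)
  slots[pos] <- gsub("/", "", calls, fixed = TRUE)
  big <- paste(slots, collapse = "")
  B2 <- 2L * geom$block_size
  starts <- (seq_len(nrow(geom$blocks)) - 1L) * B2 + 1L
  data.frame(sample_id = sample_id, experiment_id = experiment_id,
             layout = layout, chromosome = geom$blocks$chromosome,
             block_index = geom$blocks$block_index,
             payload = substring(big, starts, starts + B2 - 1L),
             stringsAsFactors = FALSE)
}

#' Write one sample's genome-wide calls into genotype blocks
#'
#' Packs the calls into one block record per (chromosome, block index)
#' spanned by the layout — the block set is layout-complete, so slots with
#' no call (and whole blocks of an all-missing sample) hold `0/0`.  Every
#' marker in `calls` must already be indexed in the layout.  Re-writing an
#' identical block is a no-op; a differing block raises a warning and the
#' stored original is kept (the commit protocol only adds new data).
#'
#' @param db a `gdb` object.
#' @param sample sample name (must be registered).
#' @param experiment experiment name.
#' @param calls data frame with columns `marker`, `allele1`, `allele2` (or
#'   `marker`, `genotype`), or a character vector of calls named by marker.
#' @param layout layout name (its index must exist, see the genome-wide
#'   importers).
#' @return Number of block records newly written.
#' @export
gdb_write_sample_blocks <- function(db, sample, experiment, calls, layout) {
  smp <- db$tables$samples
  sid <- smp$sample_id[match(sample, smp$sample_name)]
  if (is.na(sid)) stop("unknown sample: ", sample)
  eid <- gv_experiment_id(db, experiment)
  if (is.data.frame(calls)) {
    if (all(c("allele1", "allele2") %in% names(calls))) {
      cv <- normalize_call(calls$allele1, calls$allele2)
    } else if ("genotype" %in% names(calls)) {
      g <- gv_split_genotype(calls$genotype)
      cv <- normalize_call(g$a1, g$a2)
    } else stop("calls must have allele1/allele2 or genotype columns")
    ids <- resolve_marker(db, calls$marker)
  } else {
    cv <- as.character(calls)
    ids <- resolve_marker(db, names(calls))
  }
  geom <- gv_layout_geometry(db, layout)
  rows <- gv_encode_sample_rows(geom, ids, cv, sid, eid, layout)
  gv_insert_blocks(db, rows)
}

# Batched, idempotent insertion of block rows; returns number inserted.
gv_insert_blocks <- function(db, rows, warn = TRUE) {
  key <- c("sample_id", "experiment_id", "layout", "chromosome",
           "block_index")
  cur <- db$tables$genotypeblocks
  idx <- match(gv_key_string(rows, key), gv_key_string(cur, key))
  hit <- !is.na(idx)
  if (any(hit)) {
    differ <- rows$payload[hit] != cur$payload[idx[hit]]
    if (any(differ) && warn) {
      warning(sum(differ), " block(s) already stored with different ",
              "genotypes; stored originals kept", call. = FALSE)
    }
  }
  new <- rows[!hit, , drop = FALSE]
  if (nrow(new)) gv_insert(db, "genotypeblocks", new)
  nrow(new)
}

#' Read genotypes for a span of blocks
#'
#' Fetches, for each requested sample, the calls of every marker whose
#' index entry falls inside the given chromosome/block span of the layout.
#' Adjacent markers sharing a block are served by a single stored record.
#' A span outside the layout yields an empty result.
#'
#' @param db a `gdb` object.
#' @param samples character vector of sample names.
#' @param experiment experiment name.
#' @param chromosome storage chromosome number.
#' @param layout layout name.
#' @param blocks optional integer vector of 0-based block indices
#'   (default: every block of the chromosome).
#' @return A data frame with columns `sample`, `marker`, `call`.
#' @export
gdb_read_range <- function(db, samples, experiment, chromosome, layout,
                           blocks = NULL) {
  smp <- db$tables$samples
  sids <- smp$sample_id[match(samples, smp$sample_name)]
  if (anyNA(sids)) {
    stop("unknown sample(s): ",
         paste(samples[is.na(sids)], collapse = ", "))
  }
  eid <- gv_experiment_id(db, experiment)
  snp <- db$tables$snpblocks
  snp <- snp[snp$layout == layout & snp$chromosome == chromosome, ,
             drop = FALSE]
  if (!is.null(blocks)) {
    snp <- snp[snp$block_index %in% as.integer(blocks), , drop = FALSE]
  }
  if (!nrow(snp) || !length(sids)) {
    return(data.frame(sample = character(0), marker = character(0),
                      call = character(0), stringsAsFactors = FALSE))
  }
  gb <- db$tables$genotypeblocks
  gb <- gb[gb$experiment_id == eid & gb$layout == layout &
             gb$chromosome == chromosome &
             gb$sample_id %in% sids &
             gb$block_index %in% unique(snp$block_index), , drop = FALSE]
  if (!nrow(gb)) {
    return(data.frame(sample = character(0), marker = character(0),
                      call = character(0), stringsAsFactors = FALSE))
  }
  # one decoded row per (stored block, indexed marker in that block)
  j <- match(paste(gb$block_index), paste(snp$block_index))  # grouping aid
  out <- do.call(rbind, lapply(seq_len(nrow(gb)), function(i) {
    s <- snp[snp$block_index == gb$block_index[i], , drop = FALSE]
    off <- 2L * s$offset + 1L
    a1 <- substring(gb$payload[i], off, off)
    a2 <- substring(gb$payload[i], off + 1L, off + 1L)
    data.frame(sample_id = gb$sample_id[i], marker_id = s$marker_id,
               call = normalize_call(a1, a2), stringsAsFactors = FALSE)
  }))
  mk <- db$tables$markers
  data.frame(
    sample = smp$sample_name[match(out$sample_id, smp$sample_id)],
    marker = mk$name[match(out$marker_id, mk$marker_id)],
    call = out$call, stringsAsFactors = FALSE)
}

# Long-format fetch from the block store for arbitrary marker/sample sets,
# used by the merge/export pipeline.  Returns member-attributed calls.
gv_fetch_block_calls <- function(db, marker_ids, sample_ids = NULL,
                                 experiment_ids = NULL) {
  snp <- db$tables$snpblocks
  snp <- snp[snp$marker_id %in% marker_ids, , drop = FALSE]
  gb <- db$tables$genotypeblocks
  if (!is.null(sample_ids)) {
    gb <- gb[gb$sample_id %in% sample_ids, , drop = FALSE]
  }
  if (!is.null(experiment_ids)) {
    gb <- gb[gb$experiment_id %in% experiment_ids, , drop = FALSE]
  }
  if (!nrow(snp) || !nrow(gb)) {
    return(data.frame(member_id = integer(0), marker_id = integer(0),
                      experiment_id = integer(0), sample_id = integer(0),
                      call = character(0), stringsAsFactors = FALSE))
  }
  bk <- paste(snp$layout, snp$chromosome, snp$block_index, sep = "\r")
  gk <- paste(gb$layout, gb$chromosome, gb$block_index, sep = "\r")
  keep <- gk %in% bk
  gb <- gb[keep, , drop = FALSE]
  gk <- gk[keep]
  if (!nrow(gb)) {
    return(data.frame(member_id = integer(0), marker_id = integer(0),
                      experiment_id = integer(0), sample_id = integer(0),
                      call = character(0), stringsAsFactors = FALSE))
  }
  # cross join block rows x indexed markers within the same physical block
  sidx <- split(seq_len(nrow(snp)), bk)
  gidx <- split(seq_len(nrow(gb)), gk)
  pieces <- lapply(names(gidx), function(k) {
    s <- sidx[[k]]
    g <- gidx[[k]]
    ns <- length(s); ng <- length(g)
    grow <- rep(g, each = ns)
    srow <- rep(s, times = ng)
    off <- 2L * snp$offset[srow] + 1L
    pl <- gb$payload[grow]
    a1 <- substring(pl, off, off)
    a2 <- substring(pl, off + 1L, off + 1L)
    data.frame(sample_id = gb$sample_id[grow],
               experiment_id = gb$experiment_id[grow],
               marker_id = snp$marker_id[srow],
               call = normalize_call(a1, a2), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  smp <- db$tables$samples
  out$member_id <- smp$member_id[match(out$sample_id, smp$sample_id)]
  out[, c("member_id", "marker_id", "experiment_id", "sample_id", "call")]
}
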