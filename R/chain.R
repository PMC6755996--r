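#' Read a UCSC chain file
#'
#' Parses a chain-format pairwise alignment map. Coordinates in the file are
#' 0-based half-open as per the chain standard. Only plus-strand chains are
#' supported (co-linear, same-orientation alignments); a minus strand on
#' either side is a parse error.
#'
#' @param path Path to a chain file.
#' @return An object of class `grnx_chains`: a list of chains, each a list
#'   with the header fields (`score`, `t_name`, `t_size`, `t_start`, `t_end`,
#'   `q_name`, `q_size`, `q_start`, `q_end`, `id`) and a `blocks` data.frame
#'   with columns `size`, `dt`, `dq` (the last block has `dt = dq = NA`).
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  chains <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) { i <- i + 1L; next }
    f <- strsplit(line, "[ \t]+")[[1]]
    if (f[1] != "chain" || length(f) < 12L) {
      stop("chain parse error at line ", i, ": expected a 'chain' header")
    }
    hdr <- list(
      score = as.numeric(f[2]),
      t_name = f[3], t_size = as.integer(f[4]), t_strand = f[5],
      t_start = as.integer(f[6]), t_end = as.integer(f[7]),
      q_name = f[8], q_size = as.integer(f[9]), q_strand = f[10],
      q_start = as.integer(f[11]), q_end = as.integer(f[12]),
      id = if (length(f) >= 13L) f[13] else as.character(length(chains) + 1L)
    )
    if (hdr$t_strand != "+" || hdr$q_strand != "+") {
      stop("chain parse error at line ", i,
           ": only plus-strand chains are supported")
    }
    i <- i + 1L
    sizes <- integer(0); dts <- integer(0); dqs <- integer(0)
    repeat {
      if (i > n) stop("chain parse error at line ", i, ": truncated chain body")
      bl <- trimws(lines[[i]])
      if (!nzchar(bl)) stop("chain parse error at line ", i,
                            ": blank line inside chain body")
      bf <- suppressWarnings(as.integer(strsplit(bl, "[ \t]+")[[1]]))
      if (anyNA(bf)) stop("chain parse error at line ", i,
                          ": non-numeric alignment block")
      if (length(bf) == 3L) {
        if (bf[1] <= 0L) stop("chain parse error at line ", i,
                              ": zero-length aligned block")
        sizes <- c(sizes, bf[1]); dts <- c(dts, bf[2]); dqs <- c(dqs, bf[3])
        i <- i + 1L
      } else if (length(bf) == 1L) {
        if (bf[1] <= 0L) stop("chain parse error at line ", i,
                              ": zero-length aligned block")
        sizes <- c(sizes, bf[1]); dts <- c(dts, NA_integer_); dqs <- c(dqs, NA_integer_)
        i <- i + 1L
        break
      } else {
        stop("chain parse error at line ", i, ": expected 1 or 3 fields")
      }
    }
    span_t <- sum(sizes) + sum(dts, na.rm = TRUE)
    span_q <- sum(sizes) + sum(dqs, na.rm = TRUE)
    if (span_t != hdr$t_end - hdr$t_start) {
      stop("chain parse error near line ", i - 1L,
           ": block sizes/gaps do not span [t_start, t_end)")
    }
    if (span_q != hdr$q_end - hdr$q_start) {
      stop("chain parse error near line ", i - 1L,
           ": block sizes/gaps do not span [q_start, q_end)")
    }
    hdr$blocks <- data.frame(size = sizes, dt = dts, dq = dqs)
    chains[[length(chains) + 1L]] <- hdr
  }
  structure(chains, class = "grnx_chains")
}

#' Write a chain object to a UCSC chain file
#'
#' @param chains A `grnx_chains` object (see [read_chain()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chains, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ch in chains) {
    writeLines(paste("chain", format(ch$score, scientific = FALSE),
                     ch$t_name, ch$t_size, ch$t_strand, ch$t_start, ch$t_end,
                     ch$q_name, ch$q_size, ch$q_strand, ch$q_start, ch$q_end,
                     ch$id), con)
    b <- ch$blocks
    nb <- nrow(b)
    if (nb > 1L) {
      writeLines(paste(b$size[-nb], b$dt[-nb], b$dq[-nb]), con)
    }
    writeLines(as.character(b$size[nb]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Invert a chain object (swap source and target genomes)
#'
#' For plus-strand co-linear chains inversion just swaps the two coordinate
#' systems and the per-gap sizes.
#'
#' @param chains A `grnx_chains` object.
#' @return A `grnx_chains` object mapping in the opposite direction.
#' @export
invert_chain <- function(chains) {
  out <- lapply(chains, function(ch) {
    inv <- ch
    inv$t_name <- ch$q_name; inv$t_size <- ch$q_size
    inv$t_start <- ch$q_start; inv$t_end <- ch$q_end
    inv$q_name <- ch$t_name; inv$q_size <- ch$t_size
    inv$q_start <- ch$t_start; inv$q_end <- ch$t_end
    inv$blocks <- data.frame(size = ch$blocks$size,
                             dt = ch$blocks$dq, dq = ch$blocks$dt)
    inv
  })
  structure(out, class = "grnx_chains")
}

# Expand a grnx_chains object into a per-block table with absolute 0-based
# source (t) and target (q) block starts. Internal.
chain_block_table <- function(chains) {
  tabs <- lapply(seq_along(chains), function(ci) {
    ch <- chains[[ci]]
    b <- ch$blocks
    t0 <- ch$t_start + c(0L, cumsum(b$size[-nrow(b)] + b$dt[-nrow(b)]))
    q0 <- ch$q_start + c(0L, cumsum(b$size[-nrow(b)] + b$dq[-nrow(b)]))
    data.frame(chain = ci, chain_id = ch$id,
               t_name = ch$t_name, q_name = ch$q_name,
               t_start0 = t0, t_end0 = t0 + b$size, q_start0 = q0)
  })
  do.call(rbind, tabs)
}
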