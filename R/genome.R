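#' Virtual circular genome
#'
#' A virtual circular genome (VCG) is an abstract circular reference
#' sequence: no covalently circular molecule exists, the genome is
#' represented physically only by the ensemble of linear fragments mapping
#' onto its two strands. The stored sequence is the plus strand read 5'->3'
#' clockwise; the minus strand is its reverse complement. Coordinates are
#' 0-based and taken modulo the length `L`.
#'
#' Two alphabets are supported: standard RNA (`"ACGU"`, pairs A:U and G:C)
#' and the inosine variant (`"ACIU"`, pairs A:U and I:C), a genome-level
#' flag that switches both the pairing rules and the energy parameters.
#'
#' @param sequence character scalar over the alphabet; length >= 4.
#' @param alphabet `"ACGU"` or `"ACIU"`.
#' @param name genome name used in FASTA headers.
#' @return an object of class `vcg_genome` with fields `seq`, `L`,
#'   `alphabet`, `name`.
#' @examples
#' g <- vcg_genome("ACGUACGUACGUACGU")
#' g$L
#' @export
vcg_genome <- function(sequence, alphabet = c("ACGU", "ACIU"),
                       name = "vcg") {
  alphabet <- match.arg(alphabet)
  sequence <- toupper(as.character(sequence))
  stopifnot(length(sequence) == 1L, !is.na(sequence))
  L <- nchar(sequence)
  if (L < 4) stop("genome length must be >= 4")
  chars <- strsplit(sequence, "")[[1]]
  if (!all(chars %in% alphabet_bases(alphabet)))
    stop("sequence contains letters outside alphabet ", alphabet)
  structure(list(seq = sequence, L = L, alphabet = alphabet, name = name),
            class = "vcg_genome")
}

#' @export
print.vcg_genome <- function(x, ...) {
  cat("Virtual circular genome '", x$name, "': L = ", x$L,
      ", alphabet ", x$alphabet, "\n  ", x$seq, "\n", sep = "")
  invisible(x)
}

alphabet_bases <- function(alphabet) strsplit(alphabet, "")[[1]]

complement_map <- function(alphabet = "ACGU") {
  if (alphabet == "ACGU") c(A = "U", C = "G", G = "C", U = "A")
  else c(A = "U", C = "I", I = "C", U = "A")
}

#' Reverse complement under a genome alphabet
#'
#' @param seq character vector of sequences.
#' @param alphabet `"ACGU"` or `"ACIU"` (I pairs C).
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(seq, alphabet = "ACGU") {
  comp <- complement_map(alphabet)
  vapply(strsplit(toupper(seq), ""), function(x)
    paste(rev(unname(comp[x])), collapse = ""), "")
}

# Circular substring: k bases starting at 0-based position `start` on the
# requested strand. Minus-strand fragments are reported 5'->3', i.e. the
# reverse complement of the plus-strand interval they pair with.
genome_substr <- function(genome, start, k, strand = c("plus", "minus")) {
  strand <- match.arg(strand)
  L <- genome$L
  idx <- (start + seq_len(k) - 1L) %% L + 1L
  s <- paste(strsplit(genome$seq, "")[[1]][idx], collapse = "")
  if (strand == "plus") s else reverse_complement(s, genome$alphabet)
}

#' Enumerate all fragment placements on a virtual circular genome
#'
#' Generates every placement with a start at each of the `L` circle
#' positions, on both strands, for each length in `[min_len, max_len]` —
#' the complete fragment ensemble of the VCG model. Fragments may wrap the
#' origin (the circle is virtual; fragments are linear). Minus-strand
#' placements are recorded by the plus-strand interval they pair with, so
#' both strands share one coordinate frame.
#'
#' @param genome a [vcg_genome()].
#' @param min_len,max_len inclusive fragment length bounds,
#'   `1 <= min_len <= max_len <= L`. The defaults 2-12 reflect that VCG
#'   oligonucleotides are expected to top out around 10-12 nt, above which
#'   duplexes become too stable to denature.
#' @return a data.frame with columns `start` (0-based), `length`, `strand`
#'   (`"plus"`/`"minus"`), `mismatches` (all 0), and `seq`; exactly
#'   `2 * L * (max_len - min_len + 1)` rows.
#' @examples
#' g <- generate_fixture_genome(16, seed = 1)
#' nrow(enumerate_fragments(g, 2, 12))  # 352
#' @export
enumerate_fragments <- function(genome, min_len = 2, max_len = 12) {
  stopifnot(inherits(genome, "vcg_genome"))
  L <- genome$L
  if (!(min_len >= 1 && min_len <= max_len && max_len <= L))
    stop("need 1 <= min_len <= max_len <= L")
  grid <- expand.grid(start = 0:(L - 1L), length = min_len:max_len,
                      strand = c("plus", "minus"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$mismatches <- 0L
  gc2 <- strsplit(paste0(genome$seq, genome$seq), "")[[1]]
  comp <- complement_map(genome$alphabet)
  grid$seq <- vapply(seq_len(nrow(grid)), function(i) {
    chars <- gc2[grid$start[i] + seq_len(grid$length[i])]
    if (grid$strand[i] == "plus") paste(chars, collapse = "")
    else paste(rev(unname(comp[chars])), collapse = "")
  }, "")
  grid
}

#' Map an oligonucleotide onto both strands of the circle
#'
#' Scans every stranded rotation of the circle and reports all placements
#' with at most `max_mismatch` mismatches. Exact mapping
#' (`max_mismatch = 0`, the default) is the notion of genome membership
#' used throughout; mutation studies raise the tolerance explicitly.
#'
#' @param genome a [vcg_genome()].
#' @param oligo_seq character scalar, length between 1 and `L`.
#' @param max_mismatch maximum number of mismatches allowed.
#' @return data.frame of placements (`start`, `length`, `strand`,
#'   `mismatches`), sorted by (mismatches, strand, start). Zero rows if the
#'   oligo does not map.
#' @export
map_oligo <- function(genome, oligo_seq, max_mismatch = 0) {
  stopifnot(inherits(genome, "vcg_genome"))
  oligo_seq <- toupper(as.character(oligo_seq))
  k <- nchar(oligo_seq)
  if (k < 1) stop("empty oligo")
  if (k > genome$L) stop("oligo longer than genome")
  oc <- strsplit(oligo_seq, "")[[1]]
  L <- genome$L
  gc <- strsplit(genome$seq, "")[[1]]
  comp <- complement_map(genome$alphabet)
  out <- vector("list", 2L * L)
  n <- 0L
  for (start in 0:(L - 1L)) {
    idx <- (start + seq_len(k) - 1L) %% L + 1L
    sub <- gc[idx]
    mm_plus <- sum(oc != sub)
    if (mm_plus <= max_mismatch) {
      n <- n + 1L
      out[[n]] <- data.frame(start = start, length = k, strand = "plus",
                             mismatches = mm_plus,
                             stringsAsFactors = FALSE)
    }
    # minus: oligo 5'->3' equals reverse complement of the plus interval
    mm_minus <- sum(rev(oc) != unname(comp[sub]))
    if (mm_minus <= max_mismatch) {
      n <- n + 1L
      out[[n]] <- data.frame(start = start, length = k, strand = "minus",
                             mismatches = mm_minus,
                             stringsAsFactors = FALSE)
    }
  }
  if (n == 0L)
    return(data.frame(start = integer(), length = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out[seq_len(n)])
  res[order(res$mismatches, res$strand == "minus", res$start), ,
      drop = FALSE]
}

#' Per-position coverage depth of a pool over the circle
#'
#' Computes, for every circle position and strand, the expected number of
#' pool oligonucleotides (of length >= `min_len`) covering it. Oligos with
#' several exact placements have their counts distributed equally over those
#' placements, so the total depth equals the mapped molecule-length mass.
#' The genome is *intact* if every position is covered on at least one
#' strand: losing all oligos covering any region breaks the circle.
#'
#' @param genome a [vcg_genome()].
#' @param pool a [vcg_pool()].
#' @param min_len minimum oligo length that counts toward coverage.
#' @return list with `depth` (L x 2 matrix, columns plus/minus), `intact`
#'   (logical), and `unmapped` (data.frame of species with no exact
#'   placement, reported but not fatal).
#' @export
coverage_profile <- function(genome, pool, min_len = 2) {
  stopifnot(inherits(genome, "vcg_genome"), inherits(pool, "vcg_pool"))
  L <- genome$L
  depth <- matrix(0, nrow = L, ncol = 2,
                  dimnames = list(NULL, c("plus", "minus")))
  unmapped <- list()
  sp <- pool$species
  if (nrow(sp)) {
    agg <- stats::aggregate(count ~ seq, data = sp, FUN = sum)
    for (i in seq_len(nrow(agg))) {
      s <- agg$seq[i]
      if (nchar(s) < min_len) next
      pl <- map_oligo(genome, s, max_mismatch = 0)
      if (nrow(pl) == 0L) {
        unmapped[[length(unmapped) + 1L]] <-
          data.frame(seq = s, count = agg$count[i],
                     stringsAsFactors = FALSE)
        next
      }
      w <- agg$count[i] / nrow(pl)
      for (j in seq_len(nrow(pl))) {
        pos <- (pl$start[j] + seq_len(pl$length[j]) - 1L) %% L + 1L
        col <- if (pl$strand[j] == "plus") 1L else 2L
        depth[pos, col] <- depth[pos, col] + w
      }
    }
  }
  unmapped <- if (length(unmapped)) do.call(rbind, unmapped)
              else data.frame(seq = character(), count = numeric(),
                              stringsAsFactors = FALSE)
  list(depth = depth, intact = min(rowSums(depth)) > 0,
       unmapped = unmapped)
}

# Encode sequences as 0-based integer vectors for the C++ kernel.
encode_seqs <- function(seqs, alphabet = "ACGU") {
  b <- alphabet_bases(alphabet)
  lapply(strsplit(seqs, ""), function(x) match(x, b) - 1L)
}
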