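# Shared fixtures and independent oracles for the vcgsim test suite.

# Independent brute-force mapper: scan every stranded rotation of the
# circle using plain string operations (no shared code with map_oligo).
brute_force_map <- function(seq_circle, oligo, max_mm = 0,
                            alphabet = "ACGU") {
  L <- nchar(seq_circle)
  k <- nchar(oligo)
  doubled <- paste0(seq_circle, seq_circle)
  rc <- function(s) {
    from <- if (alphabet == "ACGU") "ACGU" else "ACIU"
    to <- if (alphabet == "ACGU") "UGCA" else "UICA"
    paste(rev(strsplit(chartr(from, to, s), "")[[1]]), collapse = "")
  }
  mm_count <- function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  hits <- list()
  for (start in 0:(L - 1)) {
    win <- substr(doubled, start + 1, start + k)
    m1 <- mm_count(oligo, win)
    if (m1 <= max_mm)
      hits[[length(hits) + 1]] <- data.frame(
        start = start, length = k, strand = "plus", mismatches = m1,
        stringsAsFactors = FALSE)
    m2 <- mm_count(oligo, rc(win))
    if (m2 <= max_mm)
      hits[[length(hits) + 1]] <- data.frame(
        start = start, length = k, strand = "minus", mismatches = m2,
        stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(start = integer(), length = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out[order(out$mismatches, out$strand == "minus", out$start), ,
      drop = FALSE]
}

random_seq <- function(n, alphabet = "ACGU")
  paste(sample(strsplit(alphabet, "")[[1]], n, replace = TRUE),
        collapse = "")

# A pool built directly from a species table, with fed stocks set flat.
make_pool <- function(seqs, p5 = "phosphate", p3 = "diol", count = 1,
                      volume = 1e-15, bridged_each = 0, monomers_each = 0,
                      alphabet = "ACGU") {
  sp <- data.frame(seq = seqs, p5 = p5, p3 = p3, stalled = FALSE,
                   pp = "", count = count, stringsAsFactors = FALSE)
  sp <- vcgsim:::aggregate_species(sp)
  fed <- vcgsim:::empty_fed(alphabet)
  fed$bridged[] <- bridged_each
  fed$monomers[] <- monomers_each
  vcg_pool(sp, fed = fed, volume = volume, alphabet = alphabet)
}

# Build a one-template scenario as a duplex configuration plus pool.
# `bind` is a data.frame(templ, oligo, t_start, o_start, len).
make_scenario <- function(seqs, bind, p5 = NULL, p3 = NULL,
                          bridged_each = 5) {
  n <- length(seqs)
  mol <- data.frame(seq = seqs,
                    p5 = if (is.null(p5)) rep("phosphate", n) else p5,
                    p3 = if (is.null(p3)) rep("diol", n) else p3,
                    stalled = FALSE, pp = "", stringsAsFactors = FALSE)
  config <- duplex_config(mol, bind)
  pool <- make_pool(seqs, bridged_each = bridged_each)
  pool$species <- cbind(mol, count = 1)
  list(config = config, pool = pool)
}

total_units <- function(pool) oligo_units(pool) + vcgsim:::fed_units(pool)

ledger_balance <- function(state) {
  ml <- mass_ledger(state)
  unname(ml["total"] + ml["lost_cyclized"] - ml["fed_in"])
}
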