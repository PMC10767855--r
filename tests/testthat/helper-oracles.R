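# Independent oracles for property tests. These deliberately share no code
# with the package implementation: brute-force walks, explicit DP, naive
# loops.

# --- ORF scan: test every (start position, frame) pair by walking codons ----
oracle_orf_scan <- function(seq, min_codons = 30, start_codons = "ATG") {
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  rows <- list()
  i <- 1L
  while (i + 2L <= n) {
    if (substr(seq, i, i + 2L) %in% start_codons) {
      p <- i
      repeat {
        p <- p + 3L
        if (p + 2L > n) { p <- NA_integer_; break }
        cod <- substr(seq, p, p + 2L)
        if (grepl("N", cod, fixed = TRUE)) { p <- NA_integer_; break }
        if (cod %in% stops) break
      }
      if (!is.na(p)) {
        cc <- (p + 3L - i) %/% 3L
        if (cc >= min_codons) {
          rows[[length(rows) + 1L]] <-
            data.frame(start = i, stop = p, frame = (i - 1L) %% 3L,
                       codon_count = cc)
        }
      }
    }
    i <- i + 1L
  }
  if (!length(rows)) {
    return(data.frame(frame = integer(0), t_start = integer(0),
                      t_end = integer(0), codon_count = integer(0)))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$start), , drop = FALSE]
  # one ORF per (frame, stop): the most 5' start wins
  df <- df[!duplicated(paste(df$frame, df$stop)), , drop = FALSE]
  out <- data.frame(frame = df$frame, t_start = df$start - 1L,
                    t_end = df$stop + 2L, codon_count = df$codon_count)
  out[order(out$t_start, out$t_end), , drop = FALSE]
}

random_dna <- function(n, p_n = 0) {
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
               prob = c(rep((1 - p_n) / 4, 4), p_n)), collapse = "")
}

# --- quadratic affine-gap Smith-Waterman with traceback ---------------------
oracle_local_align <- function(a, b, gap_open = 11, gap_ext = 1) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  S <- e$BLOSUM62
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  go <- gap_open + gap_ext  # first gap residue pays open + extend
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F_ <- matrix(-Inf, n + 1, m + 1)
  ptH <- matrix(0L, n + 1, m + 1)
  ptE <- matrix(0L, n + 1, m + 1)
  ptF <- matrix(0L, n + 1, m + 1)
  best <- 0; bi <- 1L; bj <- 1L
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      eo <- H[i, j - 1] - go; ee <- E[i, j - 1] - gap_ext
      E[i, j] <- max(eo, ee); ptE[i, j] <- if (eo >= ee) 1L else 2L
      fo <- H[i - 1, j] - go; fe <- F_[i - 1, j] - gap_ext
      F_[i, j] <- max(fo, fe); ptF[i, j] <- if (fo >= fe) 1L else 2L
      d <- H[i - 1, j - 1] + S[A[i - 1], B[j - 1]]
      h <- max(0, d, E[i, j], F_[i, j])
      H[i, j] <- h
      ptH[i, j] <- if (h == 0) 0L else if (h == d) 1L
                   else if (h == E[i, j]) 2L else 3L
      if (h > best) { best <- h; bi <- i; bj <- j }
    }
  }
  i <- bi; j <- bj; state <- "H"; matches <- 0L; alen <- 0L
  while (TRUE) {
    if (state == "H") {
      pt <- ptH[i, j]
      if (pt == 0L) break
      if (pt == 1L) {
        alen <- alen + 1L
        if (A[i - 1] == B[j - 1]) matches <- matches + 1L
        i <- i - 1L; j <- j - 1L
      } else if (pt == 2L) state <- "E" else state <- "F"
    } else if (state == "E") {
      alen <- alen + 1L
      st <- ptE[i, j]; j <- j - 1L
      state <- if (st == 1L) "H" else "E"
    } else {
      alen <- alen + 1L
      st <- ptF[i, j]; i <- i - 1L
      state <- if (st == 1L) "H" else "F"
    }
  }
  list(score = best, identity = if (alen > 0) matches / alen else 0)
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# --- exhaustive-threshold FDR filter ----------------------------------------
oracle_fdr <- function(psms, fdr_max) {
  best <- psms[0, , drop = FALSE]; bestn <- -1L
  for (t in sort(unique(psms$score), decreasing = TRUE)) {
    acc <- psms[psms$score >= t, , drop = FALSE]
    nt <- sum(!acc$is_decoy); nd <- sum(acc$is_decoy)
    fdr <- if (nt == 0L) Inf else nd / nt
    if (fdr < fdr_max && nt > bestn) {
      best <- acc[!acc$is_decoy, , drop = FALSE]
      bestn <- nt
    }
  }
  best
}

# --- run-length IDR scan -----------------------------------------------------
oracle_idr_scan <- function(flags, min_run) {
  out <- list()
  run_start <- NA_integer_
  for (i in seq_along(flags)) {
    if (flags[i] && is.na(run_start)) run_start <- i
    if ((!flags[i] || i == length(flags)) && !is.na(run_start)) {
      run_end <- if (flags[i]) i else i - 1L
      if (run_end - run_start + 1L >= min_run) {
        out[[length(out) + 1L]] <- c(start = run_start - 1L, end = run_end)
      }
      run_start <- NA_integer_
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  as.data.frame(do.call(rbind, out))
}

# --- variant consequence: mutate genome -> resplice -> retranslate -> diff --
oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

oracle_splice <- function(chrom_seq, ex) {
  ex <- ex[order(ex$rank), , drop = FALSE]
  parts <- substring(chrom_seq, ex$start + 1L, ex$end)
  if (ex$strand[1] == "-") parts <- vapply(parts, oracle_revcomp, character(1))
  paste(parts, collapse = "")
}

oracle_t_of_g <- function(ex, g) {
  ex <- ex[order(ex$rank), , drop = FALSE]
  cum <- 0L
  for (k in seq_len(nrow(ex))) {
    w <- ex$end[k] - ex$start[k]
    if (g >= ex$start[k] && g < ex$end[k]) {
      off <- if (ex$strand[k] == "+") g - ex$start[k] else ex$end[k] - 1L - g
      return(cum + off)
    }
    cum <- cum + w
  }
  NA_integer_
}

oracle_walk_codons <- function(seq, start0) {
  gc_tab <- Biostrings::GENETIC_CODE
  stops <- c("TAA", "TAG", "TGA")
  aas <- character(0); pos <- start0
  while (pos + 3L <= nchar(seq)) {
    cod <- substr(seq, pos + 1L, pos + 3L)
    if (cod %in% stops) {
      return(list(protein = paste(aas, collapse = ""), stop_at = pos))
    }
    aas <- c(aas, if (grepl("N", cod)) "X" else unname(gc_tab[cod]))
    pos <- pos + 3L
  }
  list(protein = paste(aas, collapse = ""), stop_at = NA_integer_)
}

# One consequence category for one (variant, ORF) pair; same behavioural
# contract as the package but via genome mutation and an independent
# resplicing/translation path.
oracle_consequence <- function(genome, ex_tx, orf, chrom, pos1, ref, alt,
                               start_codons = "ATG") {
  g0 <- pos1 - 1L
  reflen <- nchar(ref)
  gpos <- g0:(g0 + reflen - 1L)
  tpos <- vapply(gpos, function(g) oracle_t_of_g(ex_tx, g), integer(1))
  if (all(is.na(tpos))) return("non_orf")
  if (anyNA(tpos)) return("non_orf")
  t_lo <- min(tpos); t_hi <- max(tpos)
  if (t_hi - t_lo != reflen - 1L) return("non_orf")
  if (!(t_lo < orf$t_end && t_hi >= orf$t_start)) return("non_orf")
  # mutate the genome and resplice with shifted exon coordinates
  chrom_seq <- genome[[chrom]]
  stopifnot(substr(chrom_seq, g0 + 1L, g0 + reflen) == ref)
  mutated <- paste0(substr(chrom_seq, 1L, g0), alt,
                    substr(chrom_seq, g0 + reflen + 1L, nchar(chrom_seq)))
  delta <- nchar(alt) - reflen
  ex2 <- ex_tx
  ex2$start <- ifelse(ex2$start > g0, ex2$start + delta, ex2$start)
  ex2$end <- ifelse(ex2$end > g0, ex2$end + delta, ex2$end)
  mut_tx <- oracle_splice(mutated, ex2)
  if (t_lo <= orf$t_start + 2L) {
    sc <- substr(mut_tx, orf$t_start + 1L, orf$t_start + 3L)
    if (!(sc %in% start_codons)) return("start_lost")
  }
  if (delta %% 3L != 0L) return("frameshift")
  if (delta > 0L) return("inframe_insertion")
  if (delta < 0L) return("inframe_deletion")
  w <- oracle_walk_codons(mut_tx, orf$t_start)
  ref_stop <- orf$t_end - 3L
  if (is.na(w$stop_at)) return("stop_lost")
  if (w$stop_at < ref_stop) return("stop_gained")
  if (w$stop_at > ref_stop) return("stop_lost")
  if (identical(w$protein, orf$protein)) "synonymous" else "missense"
}
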