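# Independent brute-force oracles, written deliberately against the rule
# statements (explicit per-window recounts with table(), linear scans),
# not against the package's cumulative-sum implementation.

oracle_lcr <- function(sequence, params = lcr_params()) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  w <- params$window_len
  out <- data.frame(kind = character(), residues = character(),
                    start = integer(), end = integer(),
                    stringsAsFactors = FALSE)
  if (n < w) return(out)
  thr_s <- ceiling(params$single_min_frac * w)
  thr_p1 <- ceiling(params$pair_first_min_frac * w)
  thr_p2 <- ceiling(params$pair_second_min_frac * w)

  single_flags <- list()  # residue -> window starts
  pair_flags <- list()    # "AB" -> window starts
  for (i in seq_len(n - w + 1L)) {
    win <- chars[i:(i + w - 1L)]
    tab <- table(win)
    tab <- tab[names(tab) != "X"]
    for (a in names(tab)) {
      if (tab[[a]] >= thr_s) single_flags[[a]] <- c(single_flags[[a]], i)
    }
    if (length(tab) >= 2L) {
      mx <- max(tab)
      for (a in names(tab)) for (b in names(tab)) {
        if (a >= b) next
        hi <- max(tab[[a]], tab[[b]]); lo <- min(tab[[a]], tab[[b]])
        if (hi == mx && hi >= thr_p1 && lo >= thr_p2) {
          key <- paste0(a, b)
          pair_flags[[key]] <- c(pair_flags[[key]], i)
        }
      }
    }
  }

  emit <- function(starts, focal, min_run, kind) {
    covered <- rep(FALSE, n)
    for (s in starts) covered[s:(s + w - 1L)] <- TRUE
    res <- NULL
    run_start <- NA
    for (p in seq_len(n + 1L)) {
      inside <- p <= n && covered[p]
      if (inside && is.na(run_start)) run_start <- p
      if (!inside && !is.na(run_start)) {
        run_end <- p - 1L
        foc <- run_start:run_end
        foc <- foc[chars[foc] %in% focal]
        if (length(foc) > 0L) {
          a <- min(foc); b <- max(foc)
          if (b - a + 1L >= min_run) {
            res <- rbind(res, data.frame(
              kind = kind, residues = paste(focal, collapse = ""),
              start = a, end = b, stringsAsFactors = FALSE))
          }
        }
        run_start <- NA
      }
    }
    res
  }

  for (a in names(single_flags)) {
    out <- rbind(out, emit(single_flags[[a]], a,
                           params$single_min_run, "single"))
  }
  for (k in names(pair_flags)) {
    out <- rbind(out, emit(pair_flags[[k]],
                           strsplit(k, "", fixed = TRUE)[[1L]],
                           params$pair_min_run, "pair"))
  }
  out <- unique(out)
  out[order(out$start, out$kind, out$residues), , drop = FALSE]
}

# regex-based homopolymer scan
oracle_runs <- function(sequence, residue, min_len) {
  pat <- sprintf("%s{%d,}", residue, min_len)
  m <- gregexpr(pat, sequence)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(start = integer(), end = integer()))
  }
  data.frame(start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

# random sequence over a biased alphabet (4 letters heavy, rest light)
random_biased_seq <- function(len,
                              heavy = c("A", "G", "S", "T"),
                              heavy_w = 0.18, light_w = NULL) {
  light <- setdiff(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                     "N", "P", "Q", "R", "S", "T", "V", "W", "Y"), heavy)
  if (is.null(light_w)) light_w <- (1 - length(heavy) * heavy_w) / length(light)
  letters_all <- c(heavy, light)
  probs <- c(rep(heavy_w, length(heavy)), rep(light_w, length(light)))
  paste(sample(letters_all, len, replace = TRUE, prob = probs),
        collapse = "")
}

lcr_spans_key <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sort(paste(df$kind, df$residues, df$start, df$end, sep = ":"))
}

rec1 <- function(seq, id = "p1") {
  data.frame(id = id, sequence = seq, description = "",
             stringsAsFactors = FALSE)
}
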