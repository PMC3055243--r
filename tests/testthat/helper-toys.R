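## Small deterministic builders shared across test files.

BASES <- c("A", "C", "G", "T")

mutateAt <- function(s, pos, shift = 1L) {
  i <- match(s[pos], BASES)
  s[pos] <- BASES[((i - 1L + shift) %% 4L) + 1L]
  s
}

## Alignment with two species (a, b), X/Y each, showing either reciprocal
## monophyly (X vs Y fixed differences) or species pairing (a vs b fixed
## differences), plus a little private noise per row.
patternAlignment <- function(pattern = c("rm", "pairing"), L = 400L,
                             n_diag = 30L, n_private = 4L, seed = 1L) {
  pattern <- match.arg(pattern)
  set.seed(seed)
  base <- sample(BASES, L, replace = TRUE)
  diag <- sort(sample.int(L, n_diag))
  g1 <- base                       # X copies (rm) or species-a (pairing)
  g2 <- mutateAt(base, diag)       # Y copies (rm) or species-b (pairing)
  priv <- function(s) mutateAt(s, sample(setdiff(seq_len(L), diag),
                                         n_private), 2L)
  rows <- if (pattern == "rm")
    list(a_X = priv(g1), b_X = priv(g1), a_Y = priv(g2), b_Y = priv(g2))
  else
    list(a_X = priv(g1), a_Y = priv(g1), b_X = priv(g2), b_Y = priv(g2))
  GametologAlignment(do.call(rbind, rows))
}

## Fabricate a scanTopologies-like result from a vector of signatures,
## for segmentation unit tests (windows of width 500, step 400).
fakeWindows <- function(sigs, width = 500L, step = 400L) {
  n <- length(sigs)
  starts <- (seq_len(n) - 1L) * step
  w <- data.frame(window = seq_len(n), start = starts,
                  end = starts + width,
                  call = ifelse(sigs == "RM", "RECIPROCAL_MONOPHYLY",
                                ifelse(sigs == "U", "UNRESOLVED",
                                       "MIXED")),
                  signature = sigs, n_sites = width)
  attr(w, "calls") <- lapply(sigs, function(s) {
    groups <- if (s %in% c("RM", "U")) list()
    else {
      keys <- strsplit(s, ";", fixed = TRUE)[[1]]
      setNames(lapply(keys, function(k)
        list(species = strsplit(k, "+", fixed = TRUE)[[1]],
             support = 100)), keys)
    }
    structure(list(call = w$call[match(s, sigs)], signature = s,
                   groups = groups, clades = groups,
                   paired_species = sort(unique(unlist(
                     lapply(groups, `[[`, "species")))),
                   support_ok = TRUE, rm_support = NA_real_,
                   reason = NA_character_),
              class = "TopologyCall")
  })
  w
}
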