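#' Nei-Gojobori (1986) synonymous and nonsynonymous divergence
#'
#' Counting-method divergence between two codon-aligned sequences.
#' Synonymous site counts per codon are the fraction of the three possible
#' changes at each position that preserve the amino acid (changes creating a
#' stop codon count as nonsynonymous); S and N are averaged over the two
#' sequences.  For codons differing at several positions, synonymous and
#' nonsynonymous differences are averaged over all substitution pathways
#' (orderings of the differing positions), excluding pathways that pass
#' through a stop codon; if every pathway is blocked, all pathways are used.
#' Proportions are Jukes-Cantor corrected; a proportion >= 0.75 is flagged
#' as saturated and yields `NA`.
#'
#' Codons containing gaps, ambiguous bases, or a stop in either sequence are
#' skipped.
#'
#' @param seq_a,seq_b DNA strings, codon-aligned, equal length
#' @return list: Ka, Ks, Ka_Ks, S, N, Sd, Nd, p_n, p_s, n_codons_used,
#'   saturated (logical: c(nonsyn, syn))
#' @examples
#' ng86_divergence("ATGAAAGGG", "ATGAAAGGA")
#' @export
ng86_divergence <- function(seq_a, seq_b) {
  ca <- split_codons(seq_a)
  cb <- split_codons(seq_b)
  if (length(ca) != length(cb)) stop("sequences differ in codon length")
  tab <- codon_table()
  valid <- function(cd) !is.na(tab[cd]) && tab[[cd]] != "*" &&
    !grepl("[^ACGT]", cd)
  keep <- vapply(seq_along(ca), function(k) valid(ca[k]) && valid(cb[k]),
                 logical(1))
  ca <- ca[keep]; cb <- cb[keep]
  if (length(ca) == 0) stop("no usable codons")

  syn_sites <- function(cd) {
    s <- 0
    for (p in 1:3) {
      ref <- substr(cd, p, p)
      for (b in setdiff(BASES, ref)) {
        m <- cd
        substr(m, p, p) <- b
        if (tab[[m]] != "*" && tab[[m]] == tab[[cd]]) s <- s + 1 / 3
      }
    }
    s
  }
  S <- (sum(vapply(ca, syn_sites, numeric(1))) +
          sum(vapply(cb, syn_sites, numeric(1)))) / 2
  N <- 3 * length(ca) - S

  # average synonymous/nonsynonymous steps over substitution pathways
  path_counts <- function(c1, c2) {
    diffs <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    nd <- length(diffs)
    if (nd == 0) return(c(sd = 0, nd = 0))
    perms <- if (nd == 1) list(diffs) else {
      # all orderings of the differing positions
      perm_rec <- function(v) {
        if (length(v) == 1) return(list(v))
        out <- list()
        for (k in seq_along(v))
          for (rest in perm_rec(v[-k]))
            out[[length(out) + 1L]] <- c(v[k], rest)
        out
      }
      perm_rec(diffs)
    }
    tally <- function(allow_stops) {
      tot <- c(0, 0); n_used <- 0L
      for (ord in perms) {
        cur <- c1
        steps <- c(0, 0)
        blocked <- FALSE
        for (p in ord) {
          nxt <- cur
          substr(nxt, p, p) <- substr(c2, p, p)
          if (tab[[nxt]] == "*" && !allow_stops) { blocked <- TRUE; break }
          if (tab[[nxt]] == tab[[cur]] && tab[[nxt]] != "*")
            steps[1] <- steps[1] + 1 else steps[2] <- steps[2] + 1
          cur <- nxt
        }
        if (!blocked) {
          tot <- tot + steps
          n_used <- n_used + 1L
        }
      }
      list(tot = tot, n = n_used)
    }
    res <- tally(allow_stops = FALSE)
    if (res$n == 0L) res <- tally(allow_stops = TRUE)
    c(sd = res$tot[1] / res$n, nd = res$tot[2] / res$n)
  }
  cnt <- vapply(seq_along(ca), function(k) path_counts(ca[k], cb[k]),
                numeric(2))
  Sd <- sum(cnt["sd", ])
  Nd <- sum(cnt["nd", ])

  p_s <- Sd / S
  p_n <- Nd / N
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -3 / 4 * log(1 - 4 * p / 3)
  }
  Ks <- jc(p_s)
  Ka <- jc(p_n)
  list(Ka = Ka, Ks = Ks,
       Ka_Ks = if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_,
       S = S, N = N, Sd = Sd, Nd = Nd, p_n = p_n, p_s = p_s,
       n_codons_used = length(ca),
       saturated = c(nonsyn = p_n >= 0.75, syn = p_s >= 0.75))
}
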