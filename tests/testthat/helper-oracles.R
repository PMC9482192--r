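# independent oracles used by the unit and acceptance suites

# studentised-range pairwise significance computed directly from group
# means, pooled variance and ptukey (independent of stats::TukeyHSD)
tukey_oracle_sig <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  k <- nlevels(groups)
  ns <- tapply(values, groups, length)
  ms <- tapply(values, groups, mean)
  mse <- sum(tapply(values, groups, function(x)
    sum((x - mean(x))^2))) / (length(values) - k)
  dfr <- length(values) - k
  sig <- matrix(FALSE, k, k,
                dimnames = list(levels(groups), levels(groups)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- abs(ms[i] - ms[j]) / se
    p <- stats::ptukey(q, k, dfr, lower.tail = FALSE)
    sig[i, j] <- sig[j, i] <- p < alpha
  }
  sig
}

# brute-force compact letter display: enumerate maximal intervals of the
# mean ordering that contain no significant pair
letters_from_sig <- function(sig, means) {
  k <- length(means)
  ord <- order(means, decreasing = TRUE)
  sets <- list()
  for (a in seq_len(k)) for (b in a:k) {
    grp <- ord[a:b]
    if (any(sig[grp, grp])) break
    cand <- sort(grp)
    covered <- any(vapply(sets, function(s) all(cand %in% s), logical(1)))
    bigger <- b < k && !any(sig[ord[a:(b + 1)], ord[a:(b + 1)]])
    if (!covered && !bigger) sets[[length(sets) + 1]] <- cand
  }
  lets <- character(k)
  for (s in seq_along(sets)) for (g in sets[[s]])
    lets[g] <- paste0(lets[g], letters[s])
  lets
}
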