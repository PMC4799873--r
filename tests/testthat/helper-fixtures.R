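# Shared fixtures: the packaged Xq28 cohort and small builders for
# constructed cases.

fixture_map <- function() read_marker_map(founder_example("xq28_marker_map.tsv"))

fixture_table <- function() {
  read_chromosomes(c(founder_example("xq28_disease_chromosomes.tsv"),
                     founder_example("xq28_control_chromosomes_synthetic.tsv")),
                   fixture_map())
}

# cached copies (read once per test run)
FIX_MAP <- fixture_map()
FIX_TAB <- fixture_table()
FIX_ANC <- infer_ancestral(FIX_TAB)

# a minimal map: markers A (theta 0.01) and B (theta 0.05) around mutation
# at 100 Mb
tiny_map <- function() {
  marker_map(data.frame(name = c("A", "B"), position_mb = c(99, 105)),
             mutation_position_mb = 100)
}

# build a chromosome_table from an allele matrix per group
tiny_table <- function(map, disease, control = NULL) {
  mk_df <- function(m, group, prefix) {
    m <- matrix(m, ncol = nrow(map))
    colnames(m) <- map$name
    data.frame(sample_id = sprintf("%s%03d", prefix, seq_len(nrow(m))),
               family_id = sprintf("%sF%03d", prefix, seq_len(nrow(m))),
               group = group, m, check.names = FALSE)
  }
  rec <- mk_df(disease, "disease", "D")
  if (!is.null(control)) rec <- rbind(rec, mk_df(control, "control", "C"))
  chromosome_table(map, rec)
}

# independent brute-force two-sided Fisher p for a 2x2 table: enumerate all
# tables with the observed margins via factorial arithmetic (no dhyper)
fisher_bruteforce <- function(x) {
  rs <- rowSums(x); cs <- colSums(x); n <- sum(x)
  lo <- max(0, cs[1] - rs[2]); hi <- min(cs[1], rs[1])
  logp <- function(a) {
    b <- rs[1] - a; c <- cs[1] - a; d <- rs[2] - c
    (lfactorial(rs[1]) + lfactorial(rs[2]) + lfactorial(cs[1]) + lfactorial(cs[2]) -
       lfactorial(n) - lfactorial(a) - lfactorial(b) - lfactorial(c) - lfactorial(d))
  }
  lp <- vapply(lo:hi, logp, numeric(1))
  p <- exp(lp)
  sum(p[p <= p[(lo:hi) == x[1, 1]] * (1 + 1e-7)])
}

# uniform background spectrum over given alleles
uniform_bg <- function(map, alleles) {
  out <- lapply(seq_len(nrow(map)), function(i)
    setNames(rep(1 / length(alleles), length(alleles)), alleles))
  names(out) <- map$name
  out
}

# absolute-tolerance comparison (printed-value checks)
expect_close <- function(actual, expected, tol) {
  testthat::expect_lt(abs(actual - expected), tol)
}
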