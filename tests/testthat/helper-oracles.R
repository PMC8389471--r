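## Independent brute-force oracles. These deliberately avoid the code paths
## (and the stats:: helpers) used by the package implementation.

## Poisson upper tail P(X >= k | mu) by term-by-term pmf summation
oracle_pois_tail <- function(k, mu) {
    if (mu == 0) return(if (k <= 0) 1 else 0)
    if (k <= 0) return(1)
    total <- 0
    x <- k
    repeat {
        term <- exp(-mu + x * log(mu) - lgamma(x + 1))
        total <- total + term
        x <- x + 1
        if (term < 1e-18 && x > mu + 10) break
        if (x > k + 10000) break
    }
    total
}

## Benjamini-Hochberg by the sorted-threshold scan definition
oracle_bh <- function(p) {
    n <- length(p)
    o <- order(p)
    ranked <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(ranked)))
    adj <- pmin(adj, 1)
    out <- numeric(n)
    out[o] <- adj
    out
}

## Holm step-down by the sorted running-max definition
oracle_holm <- function(p) {
    n <- length(p)
    o <- order(p)
    ranked <- p[o] * (n - seq_len(n) + 1)
    adj <- cummax(pmin(ranked, 1))
    adj <- pmin(adj, 1)
    out <- numeric(n)
    out[o] <- adj
    out
}

## character-pair scan for TA sites (no pattern matching machinery)
oracle_ta_scan <- function(seq_chr) {
    chars <- strsplit(toupper(seq_chr), "")[[1]]
    n <- length(chars)
    if (n < 2) return(integer())
    which(chars[-n] == "T" & chars[-1] == "A")
}

## brute-force per-gene interval membership count
oracle_gene_hits <- function(pos, chrom, geneStart, geneEnd, geneChrom) {
    vapply(seq_along(geneStart), function(i)
        sum(chrom == geneChrom[i] & pos >= geneStart[i] & pos <= geneEnd[i]),
        integer(1))
}

## sample correlation by the closed-form sum formula
oracle_pearson <- function(x, y) {
    n <- length(x)
    num <- sum(x * y) - n * mean(x) * mean(y)
    den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
    num / den
}

## hypergeometric exclusivity tail P(overlap <= obs) for margins kA, kB of N
oracle_hyper_tail <- function(obs, kA, kB, N) {
    x <- 0:obs
    sum(choose(kA, x) * choose(N - kA, kB - x)) / choose(N, kB)
}
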