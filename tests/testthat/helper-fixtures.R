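## Shared fixture builders; everything is generated in code.

## brute-force UU counters used as oracles, independent of the package's
## run-length implementation
bruteCountUU <- function(s, mode = "nonoverlapping") {
    chars <- strsplit(s, "")[[1]]
    if (mode == "overlapping") {
        if (length(chars) < 2) return(0L)
        sum(chars[-length(chars)] == "U" & chars[-1] == "U")
    } else {
        n <- 0L; i <- 1L
        while (i < length(chars)) {
            if (chars[i] == "U" && chars[i + 1] == "U") {
                n <- n + 1L; i <- i + 2L
            } else i <- i + 1L
        }
        n
    }
}

bruteMaxWindowUU <- function(s, window, mode = "nonoverlapping") {
    L <- nchar(s)
    if (L < window) return(list(count = bruteCountUU(s, mode), start = 1L))
    counts <- vapply(seq_len(L - window + 1), function(j)
        bruteCountUU(substr(s, j, j + window - 1), mode), integer(1))
    list(count = max(counts), start = which.max(counts))
}

## brute-force Benjamini-Yekutieli step-up
bruteBY <- function(p) {
    m <- length(p)
    cm <- sum(1 / seq_len(m))
    o <- order(p)
    q <- pmin(1, m * cm * p[o] / seq_len(m))
    q <- rev(cummin(rev(q)))
    out <- numeric(m)
    out[o] <- q
    out
}

randomRNA <- function(n, uFrac = 0.25) {
    p <- c((1 - uFrac) / 3, (1 - uFrac) / 3, (1 - uFrac) / 3, uFrac)
    paste(sample(c("A", "C", "G", "U"), n, replace = TRUE, prob = p),
          collapse = "")
}

## tiny two-gene, two-tissue expression fixture
tinyCounts <- function() {
    counts <- matrix(c(100, 50, 200, 60, 120, 40, 90, 70, 80, 30, 110, 55),
                     nrow = 3,
                     dimnames = list(c("G1", "G2", "G3"),
                                     paste0("s", 1:4)))
    meta <- data.frame(sample_id = paste0("s", 1:4),
                       sex = c("female", "female", "male", "male"),
                       tissue = "blood")
    list(counts = counts, meta = meta,
         lengths = c(G1 = 1000, G2 = 2000, G3 = 500))
}

## oligo fixtures from the package's bundled FASTA
oligoSeq <- function(gene) {
    ts <- readTranscriptome(system.file("extdata", "oligos.fa",
                                        package = "tlr7scan"))
    as.character(ts)[[which(geneSymbols(ts) == gene)]]
}
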