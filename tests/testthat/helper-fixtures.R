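# Shared fixtures and independent oracles for the test suite.

# Desk-scale core-periphery connectome used across modules.
fixtureSC <- function(seed = 1L) {
    generateCorePeripherySC(40, 6, hubFactor = 5, density = 0.2,
                            seed = seed)
}

# N identical (or frequency-split) sinusoids sampled at TR = 2 s.
sinusoidBold <- function(n = 10L, freq = 0.05, nVol = 300L, tr = 2,
                         phaseOffsets = rep(0, n)) {
    tt <- seq(0, by = tr, length.out = nVol)
    vals <- t(vapply(seq_len(n), function(j)
        cos(2 * pi * freq * tt + phaseOffsets[j]), numeric(nVol)))
    boldMatrix(vals, tr)
}

# Build a PhaseMatrix directly from a phases matrix (test-only back door).
phaseFixture <- function(phases, tr = 2) {
    methods::new("PhaseMatrix", phases = phases, tr = tr)
}

# Block-diagonal clique adjacency (k cliques of size s), weight w.
cliqueMatrix <- function(k, s, w = 1) {
    n <- k * s
    m <- matrix(0, n, n)
    for (c in seq_len(k)) {
        idx <- ((c - 1) * s + 1):(c * s)
        m[idx, idx] <- w
    }
    diag(m) <- 0
    m
}

# --- Independent oracles -------------------------------------------------

# Largest connected component size by breadth-first search on an adjacency
# matrix (no igraph).
bfsLargestComponent <- function(adj) {
    n <- nrow(adj)
    seen <- rep(FALSE, n)
    best <- 0L
    for (s in seq_len(n)) {
        if (seen[s]) next
        queue <- s; seen[s] <- TRUE; size <- 0L
        while (length(queue)) {
            v <- queue[1]; queue <- queue[-1]; size <- size + 1L
            nb <- which(adj[v, ] & !seen)
            seen[nb] <- TRUE
            queue <- c(queue, nb)
        }
        best <- max(best, size)
    }
    best
}

# All set partitions of 1..n (recursive; feasible for n <= 8).
allPartitions <- function(n) {
    if (n == 1) return(list(list(1L)))
    out <- list()
    for (p in allPartitions(n - 1L)) {
        for (b in seq_along(p)) {
            q <- p
            q[[b]] <- c(q[[b]], n)
            out[[length(out) + 1L]] <- q
        }
        out[[length(out) + 1L]] <- c(p, list(n))
    }
    out
}

# Newman modularity of a partition of a binary undirected graph.
partitionModularity <- function(adj, partition) {
    m <- sum(adj[upper.tri(adj)])
    if (m == 0) return(0)
    q <- 0
    deg <- rowSums(adj)
    for (block in partition) {
        sub <- adj[block, block, drop = FALSE]
        e <- sum(sub[upper.tri(sub)])
        d <- sum(deg[block])
        q <- q + e / m - (d / (2 * m))^2
    }
    q
}

# Exhaustive-maximization modularity oracle (n <= 8).
bruteForceModularity <- function(adj) {
    max(vapply(allPartitions(nrow(adj)), partitionModularity,
               numeric(1), adj = adj))
}

# Brute-force two-sample KS statistic: scan every observed value.
bruteForceKS <- function(a, b) {
    gaps <- vapply(c(a, b), function(x)
        abs(mean(a <= x) - mean(b <= x)), numeric(1))
    max(gaps)
}
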