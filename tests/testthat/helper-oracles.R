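# Independent oracles used to check the package implementations. These
# are deliberately written as direct, brute-force restatements of the
# definitions, sharing no code with the package.

# Nx/Lx by explicit cumulative walk over the sorted lengths.
oracle_nx_lx <- function(lengths, x) {
  s <- sort(lengths, decreasing = TRUE)
  target <- x / 100 * sum(s)
  acc <- 0
  for (i in seq_along(s)) {
    acc <- acc + s[i]
    if (acc >= target) return(list(nx = s[i], lx = i))
  }
}

# BH adjusted p-values from the exhaustive closed form
# q_i = min over j >= i of min(1, p_(j) * m / j), in input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m))
    q[i] <- min(pmin(1, ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Genetic code lookup independent of the package internals.
oracle_code <- Biostrings::GENETIC_CODE

# NG86 site counts by direct mutant enumeration.
oracle_sites <- function(codon) {
  b <- strsplit(codon, "")[[1]]
  syn <- 0
  for (i in 1:3) for (alt in setdiff(c("A", "C", "G", "T"), b[i])) {
    m <- b; m[i] <- alt
    mc <- paste(m, collapse = "")
    if (oracle_code[[mc]] != "*" &&
        oracle_code[[mc]] == oracle_code[[codon]]) syn <- syn + 1 / 3
  }
  c(syn, 3 - syn)
}

# NG86 difference counts for one codon pair by recursive pathway
# enumeration: every ordering of the differing positions is a pathway;
# pathways through stop codons are dropped, and if all are dropped the
# full set is used with stop steps counted nonsynonymous.
oracle_pathways <- function(ca, cb) {
  a <- strsplit(ca, "")[[1]]; b <- strsplit(cb, "")[[1]]
  dpos <- which(a != b)
  if (!length(dpos)) return(c(0, 0))
  perms <- if (length(dpos) == 1) list(dpos) else {
    e <- expand.grid(rep(list(dpos), length(dpos)))
    e <- e[apply(e, 1, function(r) length(unique(r)) == length(dpos)), ,
           drop = FALSE]
    lapply(seq_len(nrow(e)), function(i) as.integer(e[i, ]))
  }
  count_path <- function(ord, allow_stop) {
    cur <- a; syn <- 0; non <- 0
    for (p in ord) {
      nxt <- cur; nxt[p] <- b[p]
      f <- paste(cur, collapse = ""); t <- paste(nxt, collapse = "")
      if (!allow_stop && oracle_code[[t]] == "*" && t != cb) return(NULL)
      if (oracle_code[[f]] != "*" && oracle_code[[t]] != "*" &&
          oracle_code[[f]] == oracle_code[[t]]) syn <- syn + 1
      else non <- non + 1
      cur <- nxt
    }
    c(syn, non)
  }
  res <- Filter(Negate(is.null), lapply(perms, count_path, FALSE))
  if (!length(res)) res <- lapply(perms, count_path, TRUE)
  Reduce(`+`, res) / length(res)
}

# Full NG86 dN/dS on aligned codon strings, assembled from the oracles
# above with the Jukes-Cantor formula applied literally.
oracle_ng86 <- function(sa, sb) {
  n <- nchar(sa) / 3
  starts <- 3 * (seq_len(n) - 1) + 1
  ca <- substring(sa, starts, starts + 2)
  cb <- substring(sb, starts, starts + 2)
  S <- mean(c(sum(sapply(ca, function(x) oracle_sites(x)[1])),
              sum(sapply(cb, function(x) oracle_sites(x)[1]))))
  N <- 3 * n - S
  d <- rowSums(mapply(oracle_pathways, ca, cb))
  pS <- d[1] / S; pN <- d[2] / N
  jc <- function(p) if (p >= 0.75) NA else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = d[1], Nd = d[2], pS = pS, pN = pN,
       dS = jc(pS), dN = jc(pN))
}

# Per-base depth by a literal sweep over every base.
oracle_coverage <- function(starts, ends, seq_len) {
  depth <- integer(seq_len)
  for (i in seq_along(starts))
    for (p in (starts[i] + 1):ends[i]) depth[p] <- depth[p] + 1L
  depth
}

# Union length of 1-based inclusive intervals by base marking.
oracle_union <- function(starts, ends) {
  lo <- min(starts); hi <- max(ends)
  mark <- logical(hi - lo + 1)
  for (i in seq_along(starts))
    mark[(starts[i]:ends[i]) - lo + 1] <- TRUE
  sum(mark)
}

# Exact upper hypergeometric tail by enumerating all draws.
oracle_hyper_tail <- function(N, K, n, k) {
  subsets <- utils::combn(N, n, simplify = FALSE)
  mean(sapply(subsets, function(s) sum(s <= K) >= k))
}

# Toy cluster builder shared across ortholog tests.
make_clusters <- function() {
  OrthoClusters(list(
    c1 = list(A = "a1", B = "b1", C = "c1"),
    c2 = list(A = c("a2", "a3"), B = "b2", C = "c2"),
    c3 = list(A = "a4", B = "b3"),
    c4 = list(A = "a5", B = "b4", C = "c4")), c("A", "B", "C"))
}
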