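# Shared fixtures and independent oracles, built in code.

# toy network helpers ------------------------------------------------------

toy_network <- function(pairs, scores = NULL) {
  df <- data.frame(from = pairs[, 1], to = pairs[, 2],
                   score = scores %||% rep(1, nrow(pairs)),
                   stringsAsFactors = FALSE)
  gene_network(df)
}

path_network <- function(nodes) {
  toy_network(cbind(nodes[-length(nodes)], nodes[-1]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# chromosome-2 hub/neighbor band fixture (senescence-hub neighbors with
# their printed cytogenetic locations; bold = in or bordering the
# susceptibility locus 2q33.3-2q37.2)
table_bands_fixture <- function() {
  rows <- data.frame(
    hub = c("CDKN2A", "CDKN2A", "CDKN2A", "CDKN2A", "CDKN2A",
            "TBX3", "TBX3", "TBX3", "TBX3",
            "TBX5", "TBX5", "TBX5", "TBX5", "TBX5", "TBX5", "TBX5", "TBX5"),
    gene = c("ANXA4", "CFLAR", "GULP1", "IL1A", "PDCD1",
             "CASP10", "PAX3", "RTKN", "TIA1",
             "BOK", "COL4A3", "HSPD1", "PAX3", "PDCD1", "PRKCE", "RHOB",
             "TIA1"),
    stringsAsFactors = FALSE)
  locs <- c(ANXA4 = "2p13", CFLAR = "2q33-34", GULP1 = "2q32.3-q33",
            IL1A = "2q14", PDCD1 = "2q37.3", CASP10 = "2q33-34",
            PAX3 = "2q35", RTKN = "2p13.1", TIA1 = "2p13",
            BOK = "2q37.3", COL4A3 = "2q36-37", HSPD1 = "2q33.1",
            PRKCE = "2p21", RHOB = "2p24")
  bands <- cytoband_map(names(locs), unname(locs))
  list(rows = rows, bands = bands,
       bold = c("CFLAR", "GULP1", "PDCD1", "CASP10", "PAX3", "BOK",
                "COL4A3", "HSPD1"))
}

# independent brute-force DPI oracle: enumerate all node triples ----------

brute_force_dpi_removed <- function(M, edges, tolerance) {
  genes <- rownames(M)
  if (nrow(edges) == 0 || length(genes) < 3) return(character())
  adj <- matrix(FALSE, length(genes), length(genes),
                dimnames = dimnames(M))
  for (r in seq_len(nrow(edges))) {
    adj[edges$from[r], edges$to[r]] <- TRUE
    adj[edges$to[r], edges$from[r]] <- TRUE
  }
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  removed <- character()
  trios <- utils::combn(genes, 3)
  for (cix in seq_len(ncol(trios))) {
    tri <- trios[, cix]
    if (!(adj[tri[1], tri[2]] && adj[tri[1], tri[3]] &&
          adj[tri[2], tri[3]])) next
    pair_list <- rbind(tri[c(1, 2)], tri[c(1, 3)], tri[c(2, 3)])
    vals <- c(M[tri[1], tri[2]], M[tri[1], tri[3]], M[tri[2], tri[3]])
    mn <- which.min(vals)
    others <- vals[-mn]
    if (vals[mn] < others[1] && vals[mn] < others[2] &&
        vals[mn] < (1 - tolerance) * min(others)) {
      removed <- c(removed, ekey(pair_list[mn, 1], pair_list[mn, 2]))
    }
  }
  unique(removed)
}

edge_keys <- function(from, to) paste(pmin(from, to), pmax(from, to),
                                      sep = "\r")

random_weighted_graph <- function(n_nodes, p_edge = 0.35) {
  genes <- paste0("g", seq_len(n_nodes))
  M <- matrix(0, n_nodes, n_nodes, dimnames = list(genes, genes))
  up <- which(upper.tri(M), arr.ind = TRUE)
  present <- stats::runif(nrow(up)) < p_edge
  w <- stats::runif(nrow(up), 0.05, 1)
  M[up[present, , drop = FALSE]] <- w[present]
  M <- M + t(M)
  edges <- data.frame(from = genes[up[present, 1]],
                      to = genes[up[present, 2]],
                      score = w[present], stringsAsFactors = FALSE)
  list(M = M, edges = edges)
}

# brute-force Benjamini-Hochberg step-up -----------------------------------

brute_force_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    # q for the i-th smallest: min over j >= i of m * p_(j) / j
    js <- i:m
    q[ord[i]] <- min(1, min(m * p[ord[js]] / js))
  }
  q
}
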