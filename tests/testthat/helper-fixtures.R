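# Shared in-code fixtures. Everything is constructed programmatically; no
# data files.

# three-species demethylation toy: A (CH4) -> B (CH3-) + H+ ; balanced
tiny_balanced_network <- function() {
  metabolic_network(
    list(metabolite("A", formula = "CH4", charge = 0L),
         metabolite("B", formula = "CH3", charge = -1L),
         metabolite("H", formula = "H", charge = 1L)),
    list(reaction("R1", c(A = -1, B = 1, H = 1), kind = "INTERNAL"),
         reaction("EX_A", c(A = 1), kind = "EXCHANGE", reversible = TRUE)))
}

# linear chain: A -> B -> biomass with a fixed feed of A
chain_network <- function() {
  metabolic_network(
    list(metabolite("A", formula = "CH2O", charge = 0L),
         metabolite("B", formula = "CH2O", charge = 0L),
         metabolite("biomass", formula = NA, charge = NA_integer_)),
    list(reaction("EX_A", c(A = 1), kind = "EXCHANGE", reversible = TRUE),
         reaction("AB", c(A = -1, B = 1), kind = "INTERNAL"),
         reaction("BIO", c(B = -1, biomass = 1), kind = "GROWTH")))
}

chain_exchanges <- function(feed = 1) {
  exchange_spec(parameterized = c(A = feed), secretion_only = "biomass")
}

# random gene-logic tree for round-trip property tests
random_gene_logic <- function(depth = 3) {
  if (depth == 0 || stats::runif(1) < 0.4) {
    return(haloflux:::gl_leaf(paste0("NP", sample(1000:9999, 1), "A")))
  }
  op <- sample(c("AND", "OR"), 1)
  n <- sample(2:3, 1)
  haloflux:::gl_node(op, lapply(seq_len(n), function(i)
    random_gene_logic(depth - 1)))
}

# independent vertex enumeration on {A v = b, lb <= v <= ub}, maximizing c'v;
# written separately from the package oracle so solver tests have a second,
# self-contained reference
brute_force_oracle_raw <- function(A, b, cc, lb, ub, tol = 1e-8) {
  n <- ncol(A)
  cand <- list()
  for (j in seq_len(n)) {
    if (is.finite(lb[j])) cand[[length(cand) + 1L]] <- c(j, lb[j])
    if (is.finite(ub[j])) cand[[length(cand) + 1L]] <- c(j, ub[j])
  }
  k <- n - qr(A)$rank
  best <- NULL
  if (k == 0) {
    sets <- matrix(integer(0), nrow = 0, ncol = 1)
  } else {
    sets <- utils::combn(length(cand), k)
  }
  try_point <- function(v) {
    if (any(v < lb - tol) || any(v > ub + tol)) return(NULL)
    if (max(abs(A %*% v - b)) > tol * max(1, max(abs(b)))) return(NULL)
    sum(cc * v)
  }
  eval_sets <- if (k == 0) list(integer(0)) else
    lapply(seq_len(ncol(sets)), function(i) sets[, i])
  for (sel in eval_sets) {
    Ab <- A; rhs <- b
    vars <- integer(0)
    for (s in cand[sel]) {
      row <- numeric(n); row[s[1]] <- 1
      Ab <- rbind(Ab, row); rhs <- c(rhs, s[2]); vars <- c(vars, s[1])
    }
    if (anyDuplicated(vars)) next
    qa <- qr(Ab)
    if (qa$rank < n) next
    v <- qr.coef(qa, rhs)
    if (anyNA(v)) next
    o <- try_point(v)
    if (!is.null(o) && (is.null(best) || o > best$objective)) {
      best <- list(objective = o, v = v)
    }
  }
  if (is.null(best)) list(status = "INFEASIBLE", objective = NA_real_)
  else list(status = "OPTIMAL", objective = best$objective, v = best$v)
}

unclass_all <- function(x) {
  x <- unclass(x)
  if (!is.null(x$args)) x$args <- lapply(x$args, unclass_all)
  x
}

toy_with_context <- function() {
  net <- generate_toy_network()
  list(net = net,
       exchanges = attr(net, "exchanges"),
       builder = attr(net, "growth_builder"))
}
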