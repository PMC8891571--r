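# Boolean signal-transduction network: rule parsing, synchronous dynamics,
# attractors and the receptor-input -> phenotype map.

#' Load the Boolean dependence rules of the signalling network
#'
#' Reads a tab-separated rule table (columns `node`, `class`, `expression`,
#' `reference`) describing the signal-transduction network that decides the
#' cell phenotype. Expressions use `And`, `Or`, `Not` (case-insensitive) and
#' parentheses; `Not` binds tightest, then `And`, then `Or`. Input nodes are
#' declared with the expression `External signal`.
#'
#' The default resource encodes the tumour signalling cascade downstream of
#' the six receptor-level inputs (integrin, RTK, E-cadherin, Wnt and the
#' tumour suppressors APC and NF1), with 29 internal effectors and four
#' output nodes (cell growth, proliferation, apoptosis, migration).
#'
#' @param path Path to a rule table; defaults to the packaged network.
#' @return An object of class `bn_network` with elements `nodes`, `class`
#'   (named character: external/internal/output), `rules` (named list of
#'   parsed expressions), `externals`, `internals`, `outputs` and the raw
#'   `expression` strings.
#' @export
bn_load_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "signaling_rules.tsv", package = "tumorcpm")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0L) {
    stop("rule table is empty: no nodes defined", call. = FALSE)
  }
  need <- c("node", "class", "expression")
  if (!all(need %in% names(tab))) {
    stop("rule table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  nodes <- trimws(tab$node)
  if (anyDuplicated(nodes)) {
    stop("duplicated node definitions: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "),
         call. = FALSE)
  }
  cls <- trimws(tab$class)
  names(cls) <- nodes
  rules <- vector("list", length(nodes))
  names(rules) <- nodes
  for (i in seq_along(nodes)) {
    ex <- trimws(tab$expression[i])
    if (grepl("^external signal", tolower(ex))) {
      if (cls[i] != "external") {
        stop("node '", nodes[i], "' has an external-signal rule but class '",
             cls[i], "'", call. = FALSE)
      }
      rules[[i]] <- list(op = "input", name = nodes[i])
    } else {
      if (cls[i] == "external") {
        stop("external node '", nodes[i],
             "' must not have a dependence expression (cyclic definition)",
             call. = FALSE)
      }
      rules[[i]] <- bn_parse_expression(ex, nodes)
    }
  }
  net <- structure(
    list(nodes = nodes, class = cls, rules = rules,
         externals = nodes[cls == "external"],
         internals = nodes[cls == "internal"],
         outputs = nodes[cls == "output"],
         expression = stats::setNames(trimws(tab$expression), nodes)),
    class = "bn_network")
  net
}

#' @export
print.bn_network <- function(x, ...) {
  cat("Boolean signalling network:", length(x$nodes), "nodes (",
      length(x$externals), "inputs,", length(x$internals), "internal,",
      length(x$outputs), "outputs )\n")
  invisible(x)
}

# Recursive-descent parser for And/Or/Not expressions over declared nodes.
# Grammar: or := and ('Or' and)* ; and := not ('And' not)* ;
#          not := 'Not' not | '(' or ')' | NODE
bn_parse_expression <- function(text, nodes) {
  toks <- bn_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  ast <- bn_parse_or(st, nodes)
  if (st$pos <= length(st$toks)) {
    stop("trailing tokens in expression: '", text, "'", call. = FALSE)
  }
  ast
}

bn_tokenize <- function(text) {
  text <- gsub("\\(", " ( ", text)
  text <- gsub("\\)", " ) ", text)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  if (length(toks) == 0L) stop("empty rule expression", call. = FALSE)
  toks
}

bn_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

bn_parse_or <- function(st, nodes) {
  left <- bn_parse_and(st, nodes)
  while (!is.na(bn_peek(st)) && tolower(bn_peek(st)) == "or") {
    st$pos <- st$pos + 1L
    right <- bn_parse_and(st, nodes)
    left <- list(op = "or", args = list(left, right))
  }
  left
}

bn_parse_and <- function(st, nodes) {
  left <- bn_parse_not(st, nodes)
  while (!is.na(bn_peek(st)) && tolower(bn_peek(st)) == "and") {
    st$pos <- st$pos + 1L
    right <- bn_parse_not(st, nodes)
    left <- list(op = "and", args = list(left, right))
  }
  left
}

bn_parse_not <- function(st, nodes) {
  tok <- bn_peek(st)
  if (is.na(tok)) stop("unexpected end of rule expression", call. = FALSE)
  if (tolower(tok) == "not") {
    st$pos <- st$pos + 1L
    return(list(op = "not", args = list(bn_parse_not(st, nodes))))
  }
  if (tok == "(") {
    st$pos <- st$pos + 1L
    inner <- bn_parse_or(st, nodes)
    if (is.na(bn_peek(st)) || bn_peek(st) != ")") {
      stop("unbalanced parentheses in rule expression", call. = FALSE)
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  st$pos <- st$pos + 1L
  if (!(tok %in% nodes)) {
    stop("unknown node referenced in rule: '", tok, "'", call. = FALSE)
  }
  list(op = "var", name = tok)
}

# Evaluate an AST with injectable boolean algebra (scalar/vector logical or
# packed machine words), `get(name)` returning the operand for a node.
bn_eval_ast <- function(ast, get, and, or, not) {
  switch(ast$op,
    var = get(ast$name),
    input = get(ast$name),
    not = not(bn_eval_ast(ast$args[[1]], get, and, or, not)),
    and = and(bn_eval_ast(ast$args[[1]], get, and, or, not),
              bn_eval_ast(ast$args[[2]], get, and, or, not)),
    or = or(bn_eval_ast(ast$args[[1]], get, and, or, not),
            bn_eval_ast(ast$args[[2]], get, and, or, not)),
    stop("malformed rule AST"))
}

#' Construct a network state
#'
#' Builds a full on/off assignment of every node from the six external input
#' values plus (optionally random) internal and output values. External nodes
#' are frozen during updates.
#'
#' @param net A `bn_network`.
#' @param inputs Named logical vector over (a subset of) the external nodes;
#'   unnamed externals default to `FALSE`.
#' @param internals Optional named logical vector of internal/output starting
#'   values; nodes not named are drawn uniformly at random.
#' @return Named logical vector over all nodes, class `bn_state`.
#' @export
bn_state <- function(net, inputs = NULL, internals = NULL) {
  stopifnot(inherits(net, "bn_network"))
  s <- stats::setNames(sample(c(TRUE, FALSE), length(net$nodes), replace = TRUE),
                       net$nodes)
  s[net$externals] <- FALSE
  if (!is.null(inputs)) {
    bad <- setdiff(names(inputs), net$externals)
    if (length(bad)) stop("not external inputs: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    s[names(inputs)] <- as.logical(inputs)
  }
  if (!is.null(internals)) {
    bad <- setdiff(names(internals), c(net$internals, net$outputs))
    if (length(bad)) stop("not internal nodes: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    s[names(internals)] <- as.logical(internals)
  }
  class(s) <- c("bn_state", class(s))
  s
}

#' Synchronously update a network state
#'
#' All internal and output nodes are recomputed from the previous state in
#' one step; external nodes are held fixed. With `update = "asynchronous"`
#' the nodes are instead updated one at a time in a random order (one full
#' random sweep per call), a mode intended for robustness exploration only.
#'
#' @param net A `bn_network`.
#' @param state Named logical vector over all nodes.
#' @param update `"synchronous"` (default) or `"asynchronous"`.
#' @return The next state (named logical vector).
#' @export
bn_step <- function(net, state, update = c("synchronous", "asynchronous")) {
  update <- match.arg(update)
  stopifnot(all(net$nodes %in% names(state)))
  upd <- c(net$internals, net$outputs)
  if (update == "synchronous") {
    prev <- state
    for (nd in upd) {
      state[[nd]] <- bn_eval_ast(net$rules[[nd]],
                                 get = function(nm) prev[[nm]],
                                 and = `&&`, or = `||`, not = `!`)
    }
  } else {
    for (nd in sample(upd)) {
      state[[nd]] <- bn_eval_ast(net$rules[[nd]],
                                 get = function(nm) state[[nm]],
                                 and = `&&`, or = `||`, not = `!`)
    }
  }
  state
}

#' Run the network to its attractor
#'
#' Iterates the synchronous update until a previously visited state recurs,
#' then extracts the attractor (a fixed point or a cycle) and its phenotype
#' readout.
#'
#' @param net A `bn_network`.
#' @param state Starting state (see [bn_state()]).
#' @param max_steps Maximum number of updates before giving up.
#' @param update Update scheme passed to [bn_step()].
#' @return An object of class `bn_attractor`: `states` (logical matrix, one
#'   row per attractor state), `period`, `steps` (updates until the attractor
#'   was entered) and `phenotype` (see [bn_phenotype()]).
#' @export
bn_run_to_attractor <- function(net, state, max_steps = 1000L,
                                update = "synchronous") {
  stopifnot(max_steps >= 1L)
  key <- function(s) paste(as.integer(s[net$nodes]), collapse = "")
  seen <- new.env(parent = emptyenv())
  hist <- list(state)
  assign(key(state), 1L, envir = seen)
  for (i in seq_len(max_steps)) {
    state <- bn_step(net, state, update = update)
    k <- key(state)
    if (exists(k, envir = seen, inherits = FALSE)) {
      first <- get(k, envir = seen)
      cyc <- hist[first:length(hist)]
      states <- do.call(rbind, lapply(cyc, function(s) s[net$nodes]))
      rownames(states) <- NULL
      att <- structure(list(states = states, period = nrow(states),
                            steps = first - 1L, net_outputs = net$outputs),
                       class = "bn_attractor")
      att$phenotype <- bn_phenotype(att)
      return(att)
    }
    assign(k, i + 1L, envir = seen)
    hist[[length(hist) + 1L]] <- state
  }
  stop("no attractor reached within ", max_steps, " updates", call. = FALSE)
}

#' Phenotype readout of an attractor
#'
#' The phenotype is the 4-bit code over the output nodes (growth,
#' proliferation, apoptosis, migration). For a fixed point the output bits
#' are read directly; for a cycle, a bit is on only if it is on in every
#' state of the cycle (strict-AND readout, so ambiguous oscillating outputs
#' resolve conservatively to off).
#'
#' @param attractor A `bn_attractor`.
#' @return Object of class `bn_phenotype`: named logical `bits` and the
#'   4-character `code` string such as `"1100"`.
#' @export
bn_phenotype <- function(attractor) {
  stopifnot(inherits(attractor, "bn_attractor"), nrow(attractor$states) >= 1L)
  outs <- attractor$net_outputs
  bits <- apply(attractor$states[, outs, drop = FALSE], 2, all)
  structure(list(bits = bits, code = paste(as.integer(bits), collapse = "")),
            class = "bn_phenotype")
}

#' @export
print.bn_phenotype <- function(x, ...) {
  cat("phenotype", x$code, ":",
      paste(names(x$bits)[x$bits], collapse = ", "), "\n")
  invisible(x)
}

# ---- bit-parallel machinery -------------------------------------------------
# Many trajectories are packed into machine words: bit j of word w of a
# node's value vector is the node's state in trajectory 31*w + j. Only 31
# bits per word are used because R reserves the 0x80000000 pattern for
# NA_integer_; every word stays non-negative and `Not` is masked.

bn_bits_per_word <- 31L
bn_word_all_on <- 2147483647L  # 2^31 - 1

# complement within the 31 used bits; bitwNot would produce the 0x80000000
# NA pattern for an all-on word, XOR against the mask cannot
bn_word_not <- function(x) bitwXor(x, bn_word_all_on)

bn_pack_random <- function(n_words, rng_draw) {
  hi <- rng_draw(n_words) %% 32768L        # 15 bits
  lo <- rng_draw(n_words)                  # 16 bits
  bitwOr(as.integer(hi * 65536), lo)
}

bn_popcount_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(65536L)
      for (b in 0:15) t <- t + bitwAnd(bitwShiftR(0:65535, b), 1L)
      tab <<- t
    }
    tab
  }
})

bn_popcount <- function(words, mask = NULL) {
  if (!is.null(mask)) words <- bitwAnd(words, mask)
  tab <- bn_popcount_table()
  hi <- bitwShiftR(words, 16L)  # words are always non-negative
  sum(tab[bitwAnd(words, 65535L) + 1L]) + sum(tab[hi + 1L])
}

# One synchronous step on packed words. S is a named list node -> int vector.
bn_step_packed <- function(net, S) {
  nxt <- S
  for (nd in c(net$internals, net$outputs)) {
    nxt[[nd]] <- bn_eval_ast(net$rules[[nd]],
                             get = function(nm) S[[nm]],
                             and = bitwAnd, or = bitwOr, not = bn_word_not)
  }
  nxt
}

bn_packed_run <- function(net, S, mask_last, max_steps = 200L) {
  n_words <- length(S[[1]])
  full_mask <- rep(bn_word_all_on, n_words)
  full_mask[n_words] <- mask_last
  changing <- integer(0)
  for (step in seq_len(max_steps)) {
    nxt <- bn_step_packed(net, S)
    changed <- integer(n_words)
    for (nd in c(net$internals, net$outputs)) {
      changed <- bitwOr(changed, bitwXor(nxt[[nd]], S[[nd]]))
    }
    n_chg <- bn_popcount(changed, full_mask)
    changing <- c(changing, n_chg)
    S <- nxt
    if (n_chg == 0L) return(list(S = S, changing = changing, steps = step))
  }
  stop("bit-parallel run did not reach fixed points within ", max_steps,
       " steps; the network may be cycling (use bn_run_to_attractor ",
       "per trajectory instead)", call. = FALSE)
}

# Census of the 16 possible 4-bit output codes over packed fixed points.
bn_packed_census <- function(net, S, mask_last) {
  n_words <- length(S[[1]])
  full_mask <- rep(bn_word_all_on, n_words)
  full_mask[n_words] <- mask_last
  outs <- lapply(net$outputs, function(nd) S[[nd]])
  n_out <- length(outs)
  n_codes <- 2L^n_out
  counts <- integer(n_codes)
  codes <- character(n_codes)
  for (i in seq_len(n_codes) - 1L) {
    bits <- as.logical(bitwAnd(bitwShiftR(i, (n_out - 1L):0), 1L))
    w <- full_mask
    for (j in seq_len(n_out)) {
      w <- bitwAnd(w, if (bits[j]) outs[[j]] else bn_word_not(outs[[j]]))
    }
    counts[i + 1L] <- bn_popcount(w)
    codes[i + 1L] <- paste(as.integer(bits), collapse = "")
  }
  data.frame(code = codes, count = counts)[counts > 0L, , drop = FALSE]
}

bn_random_packed_state <- function(net, inputs, n_samples) {
  bpw <- bn_bits_per_word
  n_words <- as.integer(ceiling(n_samples / bpw))
  rng_draw <- function(n) sample(65536L, n, replace = TRUE) - 1L
  S <- vector("list", length(net$nodes))
  names(S) <- net$nodes
  for (nd in net$externals) {
    S[[nd]] <- rep(if (isTRUE(inputs[[nd]])) bn_word_all_on else 0L, n_words)
  }
  for (nd in c(net$internals, net$outputs)) {
    S[[nd]] <- bn_pack_random(n_words, rng_draw)
  }
  rem <- n_samples - (n_words - 1L) * bpw
  mask_last <- if (rem == bpw) bn_word_all_on else as.integer(2^rem - 1)
  list(S = S, mask_last = mask_last)
}

#' Input-output map of the signalling network
#'
#' Evaluates the attractor phenotype for every combination of the six
#' external inputs (64 configurations). For each configuration a batch of
#' random internal starting states is run bit-parallel to its fixed point and
#' the phenotype is asserted to be independent of the internal seed.
#'
#' @param net A `bn_network`.
#' @param n_seeds Internal random starting states tested per configuration.
#' @param seed RNG seed for the internal starting states.
#' @return A data.frame with one row per input configuration: the six input
#'   bits, the phenotype `code`, the convergence step count, and `figure_map`
#'   flagging the 16 cadherin-by-(integrin,RTK,Wnt) cases with both tumour
#'   suppressors off that make up the canonical phenotype table.
#' @export
bn_input_output_map <- function(net, n_seeds = 1024L, seed = 1L) {
  stopifnot(inherits(net, "bn_network"))
  ext <- net$externals
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(ext)),
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- ext
  codes <- character(nrow(grid))
  steps <- integer(nrow(grid))
  old <- bn_set_seed(seed)
  on.exit(bn_restore_seed(old), add = TRUE)
  for (i in seq_len(nrow(grid))) {
    inp <- as.list(grid[i, , drop = FALSE])
    ps <- bn_random_packed_state(net, inp, n_seeds)
    run <- bn_packed_run(net, ps$S, ps$mask_last)
    cen <- bn_packed_census(net, run$S, ps$mask_last)
    if (nrow(cen) != 1L) {
      stop("phenotype of input configuration ", i,
           " depends on the internal starting state: ",
           paste(cen$code, collapse = ", "), call. = FALSE)
    }
    codes[i] <- cen$code
    steps[i] <- run$steps
  }
  out <- cbind(grid, code = codes, steps = steps)
  out$figure_map <- !out$APC & !out$NF1
  out
}

#' Robustness scan over internal starting states
#'
#' Samples (or exhaustively enumerates) internal starting states under given
#' external inputs, runs all of them to their attractor bit-parallel, and
#' reports the set of reached phenotypes and convergence-time statistics.
#'
#' @param net A `bn_network`.
#' @param inputs Named logical over externals, or `NULL` to scan every one of
#'   the 64 input configurations.
#' @param n_samples Random internal starting states per configuration.
#' @param seed RNG seed (the conventional census uses 1729).
#' @param exhaustive If `TRUE`, enumerate all `2^k` internal states (k =
#'   number of internal plus output nodes) instead of sampling.
#' @param guard Maximum number of states the exhaustive mode will attempt;
#'   above this an advisory error suggests sampling.
#' @return List with `phenotypes` (sorted unique codes), `census` (counts per
#'   code) and `convergence` (number of still-changing trajectories per step,
#'   summed over configurations).
#' @export
bn_robustness_scan <- function(net, inputs = NULL, n_samples = 1e5, seed = 1729L,
                               exhaustive = FALSE, guard = 2^22) {
  stopifnot(exhaustive || n_samples >= 1)
  configs <- if (is.null(inputs)) {
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(net$externals)),
                        KEEP.OUT.ATTRS = FALSE)
    names(grid) <- net$externals
    lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, , drop = FALSE]))
  } else list(as.list(inputs))
  # outputs are pure functions of the previous state, so exhausting the
  # internal nodes alone (2^29 for the shipped network) covers all dynamics
  free <- net$internals
  if (exhaustive) {
    n_states <- 2^length(free)
    if (n_states > guard) {
      stop("exhaustive enumeration of 2^", length(free), " = ",
           format(n_states, big.mark = ","), " internal states exceeds the ",
           "memory/time guard (", format(guard, big.mark = ","), "); ",
           "use sampling (exhaustive = FALSE) or raise `guard`",
           call. = FALSE)
    }
  }
  old <- bn_set_seed(seed)
  on.exit(bn_restore_seed(old), add = TRUE)
  census <- list()
  conv <- integer(0)
  for (inp in configs) {
    if (exhaustive) {
      ps <- bn_exhaustive_packed_state(net, inp, free)
    } else {
      ps <- bn_random_packed_state(net, inp, as.integer(n_samples))
    }
    run <- bn_packed_run(net, ps$S, ps$mask_last)
    cen <- bn_packed_census(net, run$S, ps$mask_last)
    census[[length(census) + 1L]] <- cen
    n <- max(length(conv), length(run$changing))
    conv <- c(conv, integer(n - length(conv)))
    ch <- c(run$changing, integer(n - length(run$changing)))
    conv <- conv + ch
  }
  all_cen <- do.call(rbind, census)
  agg <- stats::aggregate(count ~ code, data = all_cen, FUN = sum)
  list(phenotypes = sort(unique(agg$code)), census = agg, convergence = conv)
}

# Exhaustive enumeration: trajectory index bits are the initial internal
# values (node j's initial value = bit j of the trajectory index).
bn_exhaustive_packed_state <- function(net, inputs, free) {
  bpw <- bn_bits_per_word
  k <- length(free)
  n_samples <- as.integer(2^k)
  n_words <- as.integer(ceiling(n_samples / bpw))
  idx <- outer((seq_len(n_words) - 1L) * bpw, 0:(bpw - 1L), "+")
  S <- vector("list", length(net$nodes))
  names(S) <- net$nodes
  for (nd in net$externals) {
    S[[nd]] <- rep(if (isTRUE(inputs[[nd]])) bn_word_all_on else 0L, n_words)
  }
  pow2 <- 2^(0:(bpw - 1L))
  for (j in seq_along(free)) {
    bits <- bitwAnd(bitwShiftR(idx, j - 1L), 1L)
    S[[free[j]]] <- as.integer(bits %*% pow2)
  }
  for (nd in setdiff(c(net$internals, net$outputs), free)) {
    S[[nd]] <- rep(0L, n_words)
  }
  rem <- n_samples - (n_words - 1L) * bpw
  mask_last <- if (rem == bpw) bn_word_all_on else as.integer(2^rem - 1)
  list(S = S, mask_last = mask_last)
}

# seed save/restore helpers so exported functions are reproducible without
# clobbering the caller's RNG stream
bn_set_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

bn_restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
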