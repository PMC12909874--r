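# Codon-level Markov stand-in generator. Emulates the sampling interface of
# a codon-level autoregressive sequence model (prompt, temperature, top-k,
# nucleus/top-p truncation, maximum length, stop handling) so the triage
# pipeline can be exercised without any model weights.

END_TOKEN <- "<END>"
CTX_SEP <- "."
ROOT_KEY <- "-"  # key of the empty (order-0) context

context_key <- function(cods) {
  if (length(cods) == 0L) ROOT_KEY else paste(cods, collapse = CTX_SEP)
}

split_context <- function(key) {
  if (identical(key, ROOT_KEY) || identical(key, "")) character(0)
  else strsplit(key, CTX_SEP, fixed = TRUE)[[1]]
}

seq_codons_for_model <- function(x) {
  cods <- codons(x)
  stop_at <- which(cods %in% STOP_CODONS)
  if (length(stop_at) > 0L) cods <- cods[seq_len(stop_at[1])]
  cods
}

#' Fit a codon-level Markov model
#'
#' Tallies exact codon n-gram counts over a training corpus, including a
#' terminal end-of-sequence event per sequence. An in-frame stop codon
#' terminates a training sequence (matching [translate()] semantics): codons
#' past the first stop are ignored and the stop codon itself is the last
#' emission before the end event. Counts are kept at every order from 0 up
#' to `order` so that sampling can back off on unseen contexts.
#'
#' @param corpus List of [coding_sequence()] objects or character vector of
#'   DNA strings; non-empty, each sequence at least `order + 1` codons.
#' @param order Non-negative context length in codons.
#' @return Object of class `codon_markov_model`: `order`, `counts` (list
#'   indexed by order; each element maps context key to a named count
#'   vector over codons plus the end token) and `vocabulary`.
#' @export
fit_codon_markov <- function(corpus, order = 1L) {
  if (length(corpus) == 0L) stop("empty corpus")
  if (order < 0L) stop("order must be non-negative")
  order <- as.integer(order)
  seqs <- lapply(corpus, seq_codons_for_model)
  short <- which(lengths(seqs) < order + 1L)
  if (length(short) > 0L)
    stop(sprintf("sequence %d has fewer than order + 1 = %d codons",
                 short[1], order + 1L))
  counts <- lapply(seq_len(order + 1L),
                   function(i) new.env(parent = emptyenv()))
  bump <- function(env, ctx, tok) {
    cur <- env[[ctx]]
    if (is.null(cur)) cur <- numeric(0)
    cur[tok] <- if (is.na(cur[tok])) 1 else cur[tok] + 1
    env[[ctx]] <- cur
  }
  for (cods in seqs) {
    toks <- c(cods, END_TOKEN)
    n <- length(toks)
    for (k in 0:order) {
      env <- counts[[k + 1L]]
      for (t in seq.int(k + 1L, n)) {
        ctx <- if (k == 0L) ROOT_KEY
               else context_key(toks[(t - k):(t - 1L)])
        bump(env, ctx, toks[t])
      }
    }
  }
  counts <- lapply(counts, function(env) {
    out <- as.list(env)
    out[order(names(out))]
  })
  structure(list(order = order, counts = counts,
                 vocabulary = c(names(GENETIC_CODE_TABLE), END_TOKEN)),
            class = "codon_markov_model")
}

#' @export
print.codon_markov_model <- function(x, ...) {
  cat(sprintf("<codon_markov_model> order %d; %d contexts at top order\n",
              x$order, length(x$counts[[x$order + 1L]])))
  invisible(x)
}

#' Construct a codon Markov model from explicit transition counts
#'
#' Escape hatch for simulation studies: build a model directly from
#' context -> codon counts (or probabilities) without a training corpus.
#' Lower-order back-off tables are derived by marginalizing over the oldest
#' context codon.
#'
#' @param transitions Named list: context key (codons joined by `.`; `"-"`
#'   or `""` for the order-0 root) -> named numeric vector of positive
#'   counts over codons and/or the `"<END>"` token.
#' @param order Context length in codons; every context key must have
#'   exactly `order` codons.
#' @return A `codon_markov_model`.
#' @export
codon_markov_model <- function(transitions, order = 1L) {
  order <- as.integer(order)
  stopifnot(order >= 0L, is.list(transitions), !is.null(names(transitions)))
  vocab <- c(names(GENETIC_CODE_TABLE), END_TOKEN)
  for (ctx in names(transitions)) {
    v <- transitions[[ctx]]
    stopifnot(is.numeric(v), all(v > 0), all(is.finite(v)),
              !is.null(names(v)))
    if (!all(names(v) %in% vocab))
      stop("unknown tokens in context '", ctx, "'")
    nctx <- length(split_context(ctx))
    if (nctx != order)
      stop("context '", ctx, "' does not have ", order, " codons")
  }
  names(transitions)[names(transitions) == ""] <- ROOT_KEY
  counts <- vector("list", order + 1L)
  counts[[order + 1L]] <- transitions[order(names(transitions))]
  k <- order
  while (k > 0L) {
    upper <- counts[[k + 1L]]
    env <- new.env(parent = emptyenv())
    for (ctx in names(upper)) {
      sub <- context_key(split_context(ctx)[-1L])
      cur <- env[[sub]]
      if (is.null(cur)) cur <- numeric(0)
      for (tok in names(upper[[ctx]])) {
        cur[tok] <- if (is.na(cur[tok])) upper[[ctx]][[tok]]
                    else cur[tok] + upper[[ctx]][[tok]]
      }
      env[[sub]] <- cur
    }
    out <- as.list(env)
    counts[[k]] <- out[order(names(out))]
    k <- k - 1L
  }
  structure(list(order = order, counts = counts, vocabulary = vocab),
            class = "codon_markov_model")
}

#' Normalized transition probabilities of a context
#'
#' @param model A `codon_markov_model`.
#' @param context Character vector of codons (length <= model order) or a
#'   context key string; `character(0)` or `""` for the unconditional
#'   distribution.
#' @return Named probability vector summing to 1, or `NULL` if the context
#'   was never observed.
#' @export
transition_probs <- function(model, context = character(0)) {
  if (length(context) == 1L &&
      (context %in% c("", ROOT_KEY) || grepl(CTX_SEP, context, fixed = TRUE)))
    context <- split_context(context)
  k <- length(context)
  if (k > model$order) stop("context longer than model order")
  v <- model$counts[[k + 1L]][[context_key(context)]]
  if (is.null(v)) return(NULL)
  v / sum(v)
}

#' Sampling configuration
#'
#' Generation parameters of the stand-in sampler. Defaults mirror the
#' generation settings the pipeline was designed around: temperature 1.0,
#' top-k 50, nucleus top-p 0.9, at most 512 codon tokens, an ATG prompt.
#'
#' @param temperature Positive temperature; logits are scaled as
#'   `p^(1/temperature)` before truncation.
#' @param top_k Keep only the `top_k` most probable tokens (1 to 65: the 64
#'   codons plus the end token).
#' @param top_p Nucleus mass in (0, 1]: keep the smallest probability-sorted
#'   prefix with cumulative mass >= `top_p` (always at least one token).
#' @param max_codons Maximum emitted length in codons, prompt included.
#' @param prompt DNA string of whole codons that seeds generation
#'   (default "ATG").
#' @param seed Optional integer seed; identical (model, config, seed) give
#'   byte-identical samples.
#' @return Object of class `sampling_config`.
#' @export
sampling_config <- function(temperature = 1.0, top_k = 50L, top_p = 0.9,
                            max_codons = 512L, prompt = "ATG", seed = NULL) {
  stopifnot(temperature > 0, top_k >= 1L, top_k <= 65L,
            top_p > 0, top_p <= 1, max_codons >= 1L)
  prompt_cods <- codons(prompt)
  if (length(prompt_cods) < 1L) stop("prompt must contain at least one codon")
  structure(list(temperature = temperature, top_k = as.integer(top_k),
                 top_p = top_p, max_codons = as.integer(max_codons),
                 prompt = toupper(prompt), seed = seed),
            class = "sampling_config")
}

#' Temperature / top-k / top-p processing of a token distribution
#'
#' Applies, in order: temperature scaling, top-k truncation, nucleus (top-p)
#' truncation, renormalization. Probability ties are broken by token
#' lexicographic order so truncation is deterministic.
#'
#' @param probs Named probability (or weight) vector.
#' @param temperature,top_k,top_p As in [sampling_config()].
#' @return Named probability vector summing to 1, supported on at most
#'   `top_k` tokens.
#' @export
sampling_distribution <- function(probs, temperature = 1.0, top_k = 50L,
                                  top_p = 0.9) {
  stopifnot(is.numeric(probs), !is.null(names(probs)), all(probs >= 0),
            any(probs > 0))
  p <- probs / sum(probs)
  p <- p^(1 / temperature)
  p <- p / sum(p)
  p <- p[order(-p, names(p))]  # descending, lexicographic tie-break
  p <- p[seq_len(min(top_k, length(p)))]
  keep <- which(cumsum(p) >= top_p - 1e-12)[1]
  if (is.na(keep)) keep <- length(p)
  p <- p[seq_len(max(1L, keep))]
  p / sum(p)
}

sample_token <- function(dist) {
  names(dist)[sample.int(length(dist), 1L, prob = dist)]
}

# Resolve the sampling distribution for a context with back-off: drop the
# oldest codon until the context has been observed; order 0 is the
# unconditional distribution. Processed distributions are cached in `cache`.
context_distribution <- function(model, cfg, context, cache) {
  k <- min(length(context), model$order)
  context <- if (k > 0L) context[(length(context) - k + 1L):length(context)]
             else character(0)
  repeat {
    key <- paste0(k, "|", context_key(context))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    raw <- model$counts[[k + 1L]][[context_key(context)]]
    if (!is.null(raw)) {
      dist <- sampling_distribution(raw, cfg$temperature, cfg$top_k,
                                    cfg$top_p)
      cache[[key]] <- dist
      return(dist)
    }
    if (k == 0L)
      stop("no unconditional codon distribution available; empty model?")
    k <- k - 1L
    context <- if (k > 0L) context[(length(context) - k + 1L):length(context)]
               else character(0)
  }
}

#' Sample one coding sequence from a codon Markov model
#'
#' Autoregressive sampling starting from the prompt codons. At each step
#' the context distribution (after temperature / top-k / top-p processing,
#' see [sampling_distribution()]) is sampled; emission of the end token or
#' of an in-frame stop codon terminates the sequence (the stop codon is
#' retained in the DNA), as does reaching `max_codons`. Unseen contexts
#' back off by dropping the oldest codon.
#'
#' @param model A `codon_markov_model`.
#' @param cfg A [sampling_config()]; if `cfg$seed` is non-NULL the RNG is
#'   seeded, making the draw reproducible.
#' @param id Identifier of the emitted sequence.
#' @return A [coding_sequence()].
#' @export
sample_sequence <- function(model, cfg = sampling_config(), id = "sampled") {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  sample_sequence_impl(model, cfg, id,
                       cache = new.env(parent = emptyenv()))
}

sample_sequence_impl <- function(model, cfg, id, cache) {
  toks <- codons(cfg$prompt)
  if (any(toks %in% STOP_CODONS))
    return(coding_sequence(id, paste(toks[seq_len(which(
      toks %in% STOP_CODONS)[1])], collapse = "")))
  while (length(toks) < cfg$max_codons) {
    dist <- context_distribution(model, cfg, toks, cache)
    tok <- sample_token(dist)
    if (tok == END_TOKEN) break
    toks <- c(toks, tok)
    if (tok %in% STOP_CODONS) break
  }
  coding_sequence(id, paste(toks, collapse = ""))
}

#' Sample many sequences under one seed
#'
#' Seeds the RNG once from `cfg$seed` (when given) and draws `n` sequences;
#' the whole batch is reproducible.
#'
#' @inheritParams sample_sequence
#' @param n Number of sequences.
#' @param prefix Id prefix; sequences are named `<prefix>1 ... <prefix>n`.
#' @return Named character vector of DNA strings (`names` are ids).
#' @export
sample_sequences <- function(model, cfg = sampling_config(), n,
                             prefix = "gen") {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cache <- new.env(parent = emptyenv())
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- sample_sequence_impl(model, cfg, paste0(prefix, i), cache)$dna
  }
  setNames(out, paste0(prefix, seq_len(n)))
}

#' Write / read a codon Markov model as a tab-separated table
#'
#' Plain-text serialization: one row per (order, context, token, count).
#'
#' @param model A `codon_markov_model`.
#' @param path File path.
#' @return `path` invisibly for the writer; a `codon_markov_model` for the
#'   reader.
#' @export
write_markov_model <- function(model, path) {
  rows <- list()
  for (k in 0:model$order) {
    tab <- model$counts[[k + 1L]]
    for (ctx in names(tab)) {
      v <- tab[[ctx]]
      rows[[length(rows) + 1L]] <- data.frame(
        order = k, context = ctx, token = names(v), count = unname(v),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_markov_model
#' @export
read_markov_model <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(context = "character"))
  order <- max(df$order)
  counts <- vector("list", order + 1L)
  for (k in 0:order) {
    sub <- df[df$order == k, , drop = FALSE]
    tab <- lapply(split(sub, sub$context),
                  function(s) setNames(s$count, s$token))
    counts[[k + 1L]] <- tab[order(names(tab))]
  }
  structure(list(order = as.integer(order), counts = counts,
                 vocabulary = c(names(GENETIC_CODE_TABLE), END_TOKEN)),
            class = "codon_markov_model")
}
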