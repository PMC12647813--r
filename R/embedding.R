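# Sentence-embedding backends. Event descriptions are embedded as fixed-length
# vectors; pairwise cosine similarity between event embeddings defines the edge
# weights of the semantic narrative network. Two backends are provided:
#   * hash_embedder(): a deterministic signed bag-of-words hash ("feature
#     hashing") that needs no pretrained model and is the default for tests and
#     simulations;
#   * pretrained_embedder(): a thin adapter for an external sentence encoder
#     (e.g. a universal sentence encoder served from Python); it is optional
#     and the package never requires it.

# ---- 32-bit FNV-1a, exact in double arithmetic -------------------------------
# All intermediates stay below 2^53 so the modular arithmetic is exact.

.fnv_offset <- 2166136261
.fnv_prime <- 16777619

.xor32 <- function(a, b) {
  ah <- a %/% 65536L
  bh <- b %/% 65536L
  bitwXor(as.integer(ah), as.integer(bh)) * 65536 +
    bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
}

.mul32 <- function(a, b) {
  # (a * b) mod 2^32 with a < 2^32, b < 2^25
  ah <- a %/% 65536
  al <- a %% 65536
  (((ah * b) %% 65536) * 65536 + al * b) %% 4294967296
}

#' 32-bit FNV-1a hash of a token
#'
#' The documented token hash of the fallback embedding backend: the standard
#' FNV-1a iteration `h <- (h XOR byte) * 16777619 mod 2^32` over the UTF-8
#' bytes of `token`, starting from `seed` (default: the FNV offset basis
#' 2166136261). Exposed so that tests and audits can recompute bucket indices
#' and signs independently of the embedding code path.
#'
#' @param token character scalar.
#' @param seed starting state, an integer in `[0, 2^32)`.
#' @return the hash as a double holding an exact integer in `[0, 2^32)`.
#' @export
fnv1a32 <- function(token, seed = .fnv_offset) {
  stopifnot(is.character(token), length(token) == 1L)
  h <- seed
  for (byte in as.integer(charToRaw(token))) {
    h <- .mul32(.xor32(h, byte), .fnv_prime)
  }
  h
}

# Token normalization shared by the embedder: lowercase, every non-alphanumeric
# character becomes a space, split on whitespace.
.hash_tokens <- function(text) {
  text <- tolower(text)
  text <- gsub("[^a-z0-9]+", " ", text)
  tokens <- strsplit(trimws(text), "\\s+")[[1L]]
  tokens[nzchar(tokens)]
}

#' Deterministic hashing sentence embedder
#'
#' A pretrained-model-free embedding backend: each token of the normalized
#' text (lowercased, non-alphanumeric characters stripped) is mapped by
#' [fnv1a32()] to one of `dim` buckets, with a sign taken from the parity of a
#' second, independently seeded hash; token counts accumulate and each row is
#' L2-normalized. The construction is a pure function of the token multiset,
#' so it reproduces the "bag of content" geometry needed by the narrative
#' network (texts sharing vocabulary get high cosine similarity) without any
#' downloaded model.
#'
#' @param dim embedding dimension (number of hash buckets), default 512 to
#'   match the output size of common pretrained sentence encoders.
#' @return an embedder object usable with [embed_texts()].
#' @examples
#' e <- embed_texts(c("a dog ran", "the dog ran fast"), hash_embedder())
#' cosine_similarity(e$vectors[1, ], e$vectors[2, ])
#' @export
hash_embedder <- function(dim = 512L) {
  dim <- as.integer(dim)
  stopifnot(dim >= 2L)
  encode_one <- function(text) {
    v <- numeric(dim)
    for (tok in .hash_tokens(text)) {
      idx <- fnv1a32(tok) %% dim + 1
      sign <- if (fnv1a32(tok, seed = 1540483477) %% 2 == 0) 1 else -1
      v[idx] <- v[idx] + sign
    }
    v
  }
  structure(
    list(
      backend_id = sprintf("hash-fnv1a-%d", dim),
      dim = dim,
      encode = function(texts) {
        t(vapply(texts, encode_one, numeric(dim), USE.NAMES = FALSE))
      }
    ),
    class = "narrec_embedder"
  )
}

#' Adapter for a pretrained sentence encoder
#'
#' The package treats the pretrained encoder as a pluggable backend: supply
#' `encode_fun(texts)` returning an `n x dim` numeric matrix (for example a
#' wrapper around a Python universal-sentence-encoder service). Without
#' `encode_fun` this errors immediately with instructions to fall back on
#' [hash_embedder()], so that nothing in the package ever depends on a model
#' download.
#'
#' @param encode_fun function mapping a character vector to an `n x dim`
#'   matrix, or `NULL`.
#' @param dim declared output dimension.
#' @param id backend identifier recorded in the [embed_texts()] result.
#' @export
pretrained_embedder <- function(encode_fun = NULL, dim = 512L, id = "pretrained") {
  if (is.null(encode_fun)) {
    stop(
      "no pretrained sentence encoder is available in this installation; ",
      "pass encode_fun= or use the deterministic fallback hash_embedder()",
      call. = FALSE
    )
  }
  stopifnot(is.function(encode_fun))
  structure(
    list(backend_id = id, dim = as.integer(dim), encode = function(texts) {
      m <- encode_fun(texts)
      stopifnot(is.matrix(m), nrow(m) == length(texts))
      m
    }),
    class = "narrec_embedder"
  )
}

#' Embed a list of texts
#'
#' Runs the backend on `texts` and L2-normalizes every row, so cosine
#' similarity reduces to a dot product. A text with no tokens after
#' normalization yields the zero vector, with a warning (it cannot be
#' normalized and will be rejected by [build_similarity()]).
#'
#' @param texts non-empty character vector.
#' @param backend an embedder from [hash_embedder()] or
#'   [pretrained_embedder()].
#' @return an object of class `narrec_embedding`: list with `texts`,
#'   `vectors` (n x dim matrix, unit-norm rows), `backend_id`.
#' @export
embed_texts <- function(texts, backend = hash_embedder()) {
  stopifnot(is.character(texts), length(texts) >= 1L)
  if (!inherits(backend, "narrec_embedder")) {
    stop("backend must be a narrec embedder object", call. = FALSE)
  }
  vectors <- backend$encode(texts)
  norms <- sqrt(rowSums(vectors^2))
  zero <- norms == 0
  if (any(zero)) {
    warning(
      sprintf(
        "%d text(s) contain no tokens and embed to the zero vector: %s",
        sum(zero), paste(which(zero), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  vectors[!zero, ] <- vectors[!zero, , drop = FALSE] / norms[!zero]
  structure(
    list(texts = texts, vectors = vectors, backend_id = backend$backend_id),
    class = "narrec_embedding"
  )
}

#' Cosine similarity between two vectors
#'
#' `sum(u*v) / (||u|| ||v||)`, the edge-weight statistic of the semantic
#' narrative network. Symmetric and invariant to positive rescaling of either
#' argument. If both vectors are zero the similarity is defined as 0, with a
#' warning.
#'
#' @param u,v numeric vectors of equal length.
#' @return a number in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(is.numeric(u), is.numeric(v))
  if (length(u) != length(v)) {
    stop("dimension mismatch: ", length(u), " vs ", length(v), call. = FALSE)
  }
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 && nv == 0) {
    warning("cosine similarity of two zero vectors defined as 0", call. = FALSE)
    return(0)
  }
  if (nu == 0 || nv == 0) {
    return(0)
  }
  s <- sum(u * v) / (nu * nv)
  max(-1, min(1, s))
}

#' Write an embedding matrix to CSV for audit
#'
#' One row per text with columns `text, v0 ... v{D-1}`.
#'
#' @param embedding a `narrec_embedding`.
#' @param path output file.
#' @export
write_embedding_csv <- function(embedding, path) {
  stopifnot(inherits(embedding, "narrec_embedding"))
  m <- as.data.frame(embedding$vectors)
  names(m) <- paste0("v", seq_len(ncol(m)) - 1L)
  utils::write.csv(cbind(text = embedding$texts, m), path, row.names = FALSE)
  invisible(path)
}
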