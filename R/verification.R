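#' @title Multi-KRUM gradient verification
#'
#' @description
#' Each verifier scores every update in the round's transaction pool by
#' the sum of its plain Euclidean distances to its `R - f - 2` nearest
#' other updates (`R` = pool size, `f` = assumed Byzantine count); lower
#' is better.  The `R - f` lowest-scoring updates are selected as
#' qualified.  The distances are computed on the noised updates, exactly
#' what the pool contains.  Plain (unsquared) distances are the default;
#' `squared = TRUE` switches to the squared variant used by the original
#' multi-KRUM formulation for comparison.
#'
#' @param pool numeric matrix, one row per update (R x d), with optional
#'   rownames as device ids.
#' @param f assumed number of Byzantine updates; requires
#'   `nrow(pool) >= f + 3` so each update has at least one scored
#'   neighbour.
#' @param squared use squared Euclidean distances instead of plain.
#' @return `krum_scores()` returns a numeric vector of non-negative
#'   quality scores, one per row of `pool` (named like its rownames).
#' @examples
#' pool <- rbind(a = c(0, 0), b = c(0, 1), c = c(1, 0), d = c(10, 10))
#' krum_scores(pool, f = 1)
#' @export
krum_scores <- function(pool, f, squared = FALSE) {
  pool <- as.matrix(pool)
  R <- nrow(pool)
  if (R < f + 3)
    stop_param("pool too small for stated f: need R >= f + 3 (R = ", R,
               ", f = ", f, ")")
  n_nb <- R - f - 2
  D <- as.matrix(dist(pool))
  if (squared) D <- D^2
  scores <- vapply(seq_len(R), function(i) {
    sum(sort(D[i, -i], partial = n_nb)[seq_len(n_nb)])
  }, 0)
  names(scores) <- rownames(pool)
  scores
}

#' @describeIn krum_scores ids (or indices) of the `R - f` lowest-scoring
#'   updates, ties broken by ascending device id/position.
#' @param scores output of `krum_scores()` on the same pool.
#' @param ids device identifiers per row; defaults to the score names or
#'   row positions.
#' @export
select_qualified <- function(scores, f, ids = NULL) {
  R <- length(scores)
  if (R < f + 3) stop_param("pool too small for stated f")
  ids <- ids %||% (names(scores) %||% seq_len(R))
  ids[order(scores, ids)[seq_len(R - f)]]
}

#' Independent endorsement by a verification committee
#'
#' Every honest committee member independently recomputes the multi-KRUM
#' scores on the pool, selects its own qualified set, and signs the
#' canonical bytes of each update it finds qualified with its private
#' key.  Malicious members (if listed) instead sign exactly the updates
#' they should reject.  An update is accepted only when it carries valid
#' signatures from a strict majority (> M/2) of the committee, which
#' prevents a single colluding verifier from forcing its partners'
#' updates through.
#'
#' @param pool numeric matrix of noised updates (rownames = device ids).
#' @param f assumed Byzantine count passed to [krum_scores()].
#' @param committee character/integer vector of verifier ids.
#' @param keys a [party_keys()] keyring holding the committee's keys.
#' @param malicious_verifiers subset of `committee` behaving
#'   maliciously.
#' @param squared passed to [krum_scores()].
#' @return list with `accepted` (device ids with majority endorsement),
#'   `endorsements` (per device: the set of verifier signatures), and
#'   `votes` (per verifier: the qualified set it endorsed).
#' @export
endorse_and_accept <- function(pool, f, committee, keys,
                               malicious_verifiers = character(),
                               squared = FALSE) {
  M <- length(committee)
  if (M < 1) stop_param("committee must have at least one member")
  ids <- rownames(pool) %||% as.character(seq_len(nrow(pool)))
  votes <- lapply(committee, function(v) {
    sc <- krum_scores(pool, f, squared)
    qual <- select_qualified(sc, f, ids)
    if (as.character(v) %in% as.character(malicious_verifiers))
      qual <- setdiff(ids, qual)       # endorse precisely the rejects
    qual
  })
  names(votes) <- as.character(committee)
  endorsements <- lapply(ids, function(dev) {
    msg <- ser_doubles(pool[match(dev, ids), ])
    sigs <- lapply(committee[vapply(votes, function(q) dev %in% q, TRUE)],
                   function(v) list(verifier = v,
                                    sig = sign_bytes(keys, v, msg)))
    ok <- vapply(sigs, function(s)
      verify_bytes(keys, s$verifier, msg, s$sig), TRUE)
    sigs[ok]
  })
  names(endorsements) <- ids
  n_sig <- vapply(endorsements, length, 0L)
  list(accepted = ids[n_sig > M / 2],
       endorsements = endorsements,
       votes = votes)
}
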