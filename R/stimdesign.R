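#' Enumerate contextual instances
#'
#' A contextual instance is one probe sound together with an unordered pair
#' of distinct contexts drawn from silence (0) plus the N sounds.  For N
#' sounds this yields N * choose(N + 1, 2) instances: 40 for N = 4 and 550
#' for N = 10.
#'
#' @param nSounds integer N >= 1.
#' @return data.frame with columns \code{probe}, \code{contextA},
#'   \code{contextB} (contextA < contextB) and \code{instance} (a stable
#'   label \code{"ctxA:ctxB->probe"}).
#' @examples
#' nrow(enumerateInstances(4))   # 40
#' nrow(enumerateInstances(10))  # 550
#' @export
enumerateInstances <- function(nSounds) {
  nSounds <- as.integer(nSounds)
  if (length(nSounds) != 1L || is.na(nSounds) || nSounds < 1L)
    stop("nSounds must be a single integer >= 1")
  ctx <- 0:nSounds
  pairs <- utils::combn(ctx, 2L)
  out <- expand.grid(pair = seq_len(ncol(pairs)), probe = seq_len(nSounds),
                     KEEP.OUT.ATTRS = FALSE)
  df <- data.frame(probe = out$probe,
                   contextA = pairs[1L, out$pair],
                   contextB = pairs[2L, out$pair])
  df <- df[order(df$probe, df$contextA, df$contextB), , drop = FALSE]
  rownames(df) <- NULL
  df$instance <- sprintf("%d:%d->%d", df$contextA, df$contextB, df$probe)
  df
}

## Ordered (context, probe) events realized by a sequence set: the initial
## sound of each sequence is a probe in silence context; every adjacent pair
## is a (context, probe) event.
sequenceEvents <- function(seqset) {
  do.call(rbind, lapply(seq_along(seqset@sequences), function(k) {
    s <- seqset@sequences[[k]]
    data.frame(sequence = k,
               position = seq_along(s),            # 1-based position of the probe
               context = c(0L, s[-length(s)]),
               probe = s)
  }))
}

#' Validate an exact-cover sequence design
#'
#' Checks the structural invariants of a \linkS4class{SequenceSet}: N
#' sequences of N+1 in-range sounds, distinct sequence-initial sounds (each
#' sound gets its silence context exactly once), and exact single coverage of
#' all N(N+1) ordered (context, probe) events.
#'
#' @param seqset a \linkS4class{SequenceSet} (validity is *not* assumed).
#' @return list with \code{valid} (logical), \code{problems} (character),
#'   \code{missing} and \code{duplicated} (data.frames of (context, probe)
#'   events).
#' @export
validateSequences <- function(seqset) {
  n <- seqset@nSounds
  problems <- character()
  structural <- FALSE
  if (length(seqset@sequences) != n) {
    problems <- c(problems, sprintf("expected %d sequences, found %d",
                                    n, length(seqset@sequences)))
    structural <- TRUE
  }
  lens <- lengths(seqset@sequences)
  if (any(lens != n + 1L)) {
    problems <- c(problems, sprintf("sequence length(s) %s != N+1 = %d",
                                    paste(unique(lens[lens != n + 1L]), collapse = ","),
                                    n + 1L))
    structural <- TRUE
  }
  ids <- unlist(seqset@sequences)
  if (length(ids) && (any(ids < 1L) || any(ids > n)))
    problems <- c(problems, "sound ids out of range 1..N")
  firsts <- vapply(seqset@sequences, function(s) s[1L], integer(1))
  if (!structural && !setequal(firsts, seq_len(n)))
    problems <- c(problems, "sequence-initial sounds are not exactly {1..N}")

  missing <- duplicated <- data.frame(context = integer(), probe = integer())
  if (!structural) {
    ev <- sequenceEvents(seqset)
    key <- paste(ev$context, ev$probe)
    want <- expand.grid(context = 0:n, probe = seq_len(n), KEEP.OUT.ATTRS = FALSE)
    wkey <- paste(want$context, want$probe)
    tab <- table(key)
    dup <- names(tab)[tab > 1L]
    mis <- setdiff(wkey, names(tab))
    if (length(dup)) {
      duplicated <- want[wkey %in% dup, , drop = FALSE]
      problems <- c(problems, sprintf("%d duplicated (context, probe) event(s)", length(dup)))
    }
    if (length(mis)) {
      missing <- want[wkey %in% mis, , drop = FALSE]
      problems <- c(problems, sprintf("%d missing (context, probe) event(s)", length(mis)))
    }
  }
  rownames(missing) <- rownames(duplicated) <- NULL
  list(valid = length(problems) == 0L, problems = problems,
       missing = missing, duplicated = duplicated)
}

## Random Eulerian circuit (Hierholzer) of the complete digraph with
## self-loops on vertices 1..n; every vertex has in- and out-degree n.
.eulerCircuit <- function(n, start) {
  ## remaining[[v]] = successors not yet used, in randomized order
  remaining <- lapply(seq_len(n), function(v) sample(rep(seq_len(n), 1L)))
  nxt <- vapply(remaining, length, integer(1)) # pointer-free: pop from tail
  stack <- integer(n * n + 1L); stack[1L] <- start; top <- 1L
  circuit <- integer(n * n + 1L); ci <- 0L
  while (top > 0L) {
    v <- stack[top]
    if (nxt[v] > 0L) {
      u <- remaining[[v]][nxt[v]]
      nxt[v] <- nxt[v] - 1L
      top <- top + 1L
      stack[top] <- u
    } else {
      ci <- ci + 1L
      circuit[ci] <- v
      top <- top - 1L
    }
  }
  rev(circuit[seq_len(ci)])
}

#' Design balanced context-probe sequences by exact cover
#'
#' Constructs N sequences of N+1 one-second sounds such that every ordered
#' (context, probe) combination -- including silence as a context, realized
#' once for each sound at a sequence start -- occurs exactly once.  The
#' coverage problem is solved by decomposing the complete digraph with
#' self-loops on the N sounds (an Eulerian multigraph: each vertex has in-
#' and out-degree N) into one Eulerian circuit, then cutting the circuit into
#' N paths of N edges whose start vertices are all distinct; circuits are
#' redrawn under the seeded generator until a valid cut exists.
#'
#' @param library a \linkS4class{SoundLibrary}, or an integer N as shorthand.
#' @param seed integer seed; the design is deterministic given the seed.
#' @return a validated \linkS4class{SequenceSet}.
#' @examples
#' designSequences(4, seed = 1)
#' @export
designSequences <- function(library, seed = 1L) {
  n <- if (is(library, "SoundLibrary")) length(library@soundIds)
       else as.integer(library)
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("need a SoundLibrary or an integer N >= 1")
  seed <- as.integer(seed)
  seqs <- local({
    ok <- FALSE; out <- NULL
    set.seed(seed)
    for (attempt in seq_len(1000L)) {
      circ <- .eulerCircuit(n, start = sample.int(n, 1L))
      ## circ has n^2+1 vertices (first == last); edges k: circ[k]->circ[k+1]
      verts <- circ[-length(circ)]                  # n^2 vertices, cyclic
      ## try all rotations: cut points at positions 1 + k*n
      for (rot in 0L:(n * n - 1L)) {
        idx <- ((seq_len(n * n) + rot - 1L) %% (n * n)) + 1L
        v <- verts[idx]
        starts <- v[1L + (0:(n - 1L)) * n]
        if (!anyDuplicated(starts)) {
          out <- lapply(seq_len(n), function(k) {
            pos <- ((k - 1L) * n + 1L):(k * n)
            c(v[pos], v[if (k == n) 1L else k * n + 1L])
          })
          ok <- TRUE
          break
        }
      }
      if (ok) break
    }
    if (!ok) stop("unsatisfiable-design: no valid circuit cut found")
    out
  })
  ss <- new("SequenceSet", nSounds = n, sequences = seqs, seed = seed)
  rep <- validateSequences(ss)
  if (!rep$valid)
    stop("internal error: designed sequences fail validation: ",
         paste(rep$problems, collapse = "; "))
  ss
}

#' Serialize / read a SequenceSet as JSON
#'
#' @param seqset a \linkS4class{SequenceSet}.
#' @param path file path.
#' @return \code{writeSequenceSet} returns \code{path} invisibly;
#'   \code{readSequenceSet} returns a \linkS4class{SequenceSet}.
#' @export
writeSequenceSet <- function(seqset, path) {
  obj <- list(n_sounds = seqset@nSounds, seed = seqset@seed,
              sequences = seqset@sequences)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSequenceSet
#' @export
readSequenceSet <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  seqs <- obj$sequences
  if (is.matrix(seqs)) seqs <- lapply(seq_len(nrow(seqs)), function(i) as.integer(seqs[i, ]))
  else seqs <- lapply(seqs, as.integer)
  new("SequenceSet", nSounds = as.integer(obj$n_sounds),
      sequences = seqs, seed = as.integer(obj$seed))
}
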