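# internal helpers shared across modules

#' Default forearm channel labels
#'
#' Seven-channel montage: five wrist muscles (extensor carpi radialis and
#' ulnaris, flexor carpi ulnaris and radialis, abductor pollicis longus) and
#' two extrinsic finger flexors (flexor digitorum superficialis and
#' profundus) that carry the grip signal.
#'
#' @return Character vector of length 7.
#' @export
forearm_channels <- function() {
  c("ECR", "ECU", "FCU", "FCR", "APL", "FDS", "FDP")
}

#' Grip-related channel labels
#'
#' @return Character vector naming the finger-flexor channels.
#' @export
grip_channel_labels <- function() c("FDS", "FDP")

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stopf("`%s` must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stopf("`%s` must be a single positive number", name)
  }
  as.numeric(x)
}

as_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1L)
}

# cosine similarity between two vectors; 0 if either is the zero vector
cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# all permutations of 1..n as rows (n <= 8 guarded; used for exact
# assignment when matching small synergy sets)
all_permutations <- function(n) {
  if (n > 8L) stopf("permutation enumeration limited to n <= 8 (got %d)", n)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub)))
  }
  do.call(rbind, out)
}
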