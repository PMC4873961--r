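# Independent oracles used across the suite. These deliberately reimplement
# the checked quantities by brute force, not by calling package internals.

# O(n^2) pairwise concordance: P(score_case > score_control) + 1/2 ties
oracle_auc <- function(probs, outcomes) {
  pos <- probs[outcomes == 1]
  neg <- probs[outcomes == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# direct transcription of the published probability formula
oracle_prob <- function(logit) exp(logit) / (1 + exp(logit))

# exhaustive Youden scan over candidate thresholds (rule: score >= t)
oracle_youden_j <- function(probs, outcomes, t) {
  sens <- sum(probs >= t & outcomes == 1) / sum(outcomes == 1)
  spec <- sum(probs < t & outcomes == 0) / sum(outcomes == 0)
  sens + spec - 1
}

# an independently coded Robson truth table used by the partition property:
# straight transcription of the group definitions, one `if` per group, in a
# different order from the package's cascade
oracle_robson <- function(parity, previous_cs, multiple, presentation,
                          ga, onset) {
  single <- !multiple
  ceph <- single && presentation == "cephalic"
  term <- ga >= 37
  scar <- previous_cs >= 1
  nulli <- parity == 0
  spont <- onset == "spontaneous"
  if (ceph && term && nulli && spont && !scar) return(1L)
  if (ceph && term && nulli && !spont && !scar) return(2L)
  if (ceph && term && !nulli && !scar && spont) return(3L)
  if (ceph && term && !nulli && !scar && !spont) return(4L)
  if (ceph && term && scar) return(5L)
  if (single && presentation == "breech" && nulli) return(6L)
  if (single && presentation == "breech" && !nulli) return(7L)
  if (multiple) return(8L)
  if (single && presentation %in% c("transverse_oblique", "other")) return(9L)
  if (ceph && !term) return(10L)
  NA_integer_
}

# a complete-field data.frame covering every discrete input combination
robson_grid <- function() {
  g <- expand.grid(
    parity = c(0L, 2L),
    previous_cs = c(0L, 1L),
    multiple_pregnancy = c(FALSE, TRUE),
    presentation = c("cephalic", "breech", "transverse_oblique"),
    gestational_age = c(34L, 39L),
    onset_of_labour = c("spontaneous", "induced", "prelabour_cs"),
    stringsAsFactors = FALSE)
  # respect the record invariant: a previous CS implies parity > 0
  g <- g[!(g$previous_cs > 0 & g$parity == 0), ]
  rownames(g) <- NULL
  g
}

# small in-memory dataset of n group-1-style women with a given CS count
flat_dataset <- function(n, n_cs, facility_id = "f1") {
  rec <- data.frame(
    record_id = sprintf("%s_%04d", facility_id, seq_len(n)),
    facility_id = facility_id,
    parity = 0L, previous_cs = 0L, multiple_pregnancy = FALSE,
    onset_of_labour = "spontaneous", presentation = "cephalic",
    gestational_age = 39L,
    mode_of_delivery = rep(c("caesarean", "vaginal"), c(n_cs, n - n_cs)),
    stringsAsFactors = FALSE)
  facility_dataset(rec)
}
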