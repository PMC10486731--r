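# Shared fixtures: tiny volumes, random probability vectors, small models.

tiny_volume <- function(dims = c(10, 10, 10, 2), seed = 1) {
  set.seed(seed)
  array(runif(prod(dims)), dim = dims)
}

random_prob <- function(n = 6) {
  p <- rgamma(n, shape = 0.8)
  p / sum(p)
}

tiny_backbone <- function(arch = "resnet50_3d", in_channels = 2, seed = 1) {
  build_backbone(backbone_spec(arch, in_channels = in_channels,
                               width_mult = 0.25), seed = seed)
}

# Exhaustive pair-counting AUC oracle (ties count half).
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Independent kappa recomputation, written against the formula directly.
kappa_oracle <- function(cm) {
  n <- sum(cm)
  p0 <- sum(diag(cm)) / n
  pe <- as.numeric(rowSums(cm) %*% colSums(cm)) / n^2
  (p0 - pe) / (1 - pe)
}

fake_prediction <- function(p) {
  structure(list(crop_probs = matrix(p, 1), prob = p,
                 task_scores = task_score(p),
                 grade = as.integer(which.max(p) - 1L)),
            class = "octa_eye_prediction")
}
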