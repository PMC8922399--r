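#' @title Reverse-mode gradients for the attentive network
#' @description Hand-written backpropagation mirroring [mt_forward()]. Each
#'   block (linear, LeakyReLU, grouped softmax, grouped sum, GRU cell) has
#'   its adjoint applied in reverse order; correctness is checked against
#'   central finite differences in the test suite.
#' @name backprop
#' @keywords internal
NULL

lrelu_grad <- function(x, slope) ifelse(x > 0, 1, slope)

gru_backward <- function(dh2, gc, g) {
  z <- gc$z; r <- gc$r; q <- gc$q; nn <- gc$nn; x <- gc$x; h_in <- gc$h_in
  dz <- dh2 * (h_in - nn)
  dnn <- dh2 * (1 - z)
  dh <- dh2 * z
  dnn_pre <- dnn * (1 - nn^2)
  dr <- dnn_pre * q
  dq <- dnn_pre * r
  dz_pre <- dz * z * (1 - z)
  dr_pre <- dr * r * (1 - r)
  dx <- dnn_pre %*% t(g$Wh) + dz_pre %*% t(g$Wz) + dr_pre %*% t(g$Wr)
  dh <- dh + dq %*% t(g$Uh) + dz_pre %*% t(g$Uz) + dr_pre %*% t(g$Ur)
  grads <- list(
    Wz = t(x) %*% dz_pre, Uz = t(h_in) %*% dz_pre, bz = colSums(dz_pre),
    Wr = t(x) %*% dr_pre, Ur = t(h_in) %*% dr_pre, br = colSums(dr_pre),
    Wh = t(x) %*% dnn_pre, Uh = t(h_in) %*% dq,
    bhx = colSums(dnn_pre), bhh = colSums(dq))
  list(dx = dx, dh = dh, grads = grads)
}

add_gru_grads <- function(a, b) Map(`+`, a, b)

seg_softmax_backward <- function(dalign, align, gf) {
  inner <- rowsum(align * dalign, gf)
  align * (dalign - as.numeric(inner)[as.integer(gf)])
}

#' Gradients of a scalar loss w.r.t. all model parameters
#'
#' @param forward Output of `mt_forward(..., keep_cache = TRUE)`.
#' @param dpred Gradient of the loss w.r.t. the prediction matrix.
#' @param model `mt_model`.
#' @param return_datom Also return the gradient w.r.t. the final atom states
#'   (used for gradient-saliency attribution).
#' @return List of gradients with the same structure as the parameters
#'   (plus `datom` when requested).
#' @keywords internal
mt_backward <- function(forward, dpred, model, return_datom = FALSE) {
  cache <- forward$cache
  stopifnot(!is.null(cache))
  p <- model$params
  cfg <- model$config
  slope <- cfg$leakyrelu_slope
  b <- cache$batch
  A <- nrow(b$x)
  D <- cfg$graph_feat_size
  gf_edge <- cache$gf_edge
  gf_mol <- cache$gf_mol
  gf_src <- factor(cache$edge_src, levels = seq_len(A))

  g <- list()
  g$Wout <- t(cache$s_drop) %*% dpred
  g$bout <- colSums(dpred)
  ds <- dpred %*% t(p$Wout)
  if (!is.null(cache$keep)) ds <- ds * cache$keep

  read <- p$read
  gread <- list(Wrs = 0 * read$Wrs, Wrh = 0 * read$Wrh,
                ar1 = 0 * read$ar1, ar2 = 0 * read$ar2,
                gru = lapply(read$gru, function(w) 0 * w))
  dPh <- matrix(0, A, D)
  Ph <- cache$Ph
  for (t in rev(seq_along(cache$reads))) {
    rc <- cache$reads[[t]]
    gb <- gru_backward(ds, rc$gru, read$gru)
    gread$gru <- add_gru_grads(gread$gru, gb$grads)
    dcvec <- gb$dx
    ds <- gb$dh
    # cvec = rowsum(align * Ph); align is an atom-length vector
    dalign <- rowSums(dcvec[b$mol_index, , drop = FALSE] * Ph)
    dPh <- dPh + rc$align * dcvec[b$mol_index, , drop = FALSE]
    dlogit <- seg_softmax_backward(dalign, rc$align, gf_mol)
    dlogit_pre <- dlogit * lrelu_grad(rc$logit_pre, slope)
    dps <- as.numeric(rowsum(dlogit_pre, gf_mol))
    dPs <- outer(dps, read$ar1)
    gread$ar1 <- gread$ar1 + colSums(rc$Ps * dps)
    dPh <- dPh + outer(dlogit_pre, read$ar2)
    gread$ar2 <- gread$ar2 + colSums(Ph * dlogit_pre)
    ds <- ds + dPs %*% t(read$Wrs)
    gread$Wrs <- gread$Wrs + t(rc$s_in) %*% dPs
  }
  # s0 = rowsum(h)/n_atoms
  dh <- (ds / b$n_atoms)[b$mol_index, , drop = FALSE]
  dh <- dh + dPh %*% t(read$Wrh)
  gread$Wrh <- gread$Wrh + t(cache$h_final) %*% dPh
  g$read <- gread
  if (return_datom) g$datom <- dh

  g$layers <- vector("list", length(p$layers))
  for (l in rev(seq_along(p$layers))) {
    lp <- p$layers[[l]]
    lc <- cache$layers[[l]]
    gb <- gru_backward(dh, lc$gru, lp$gru)
    dC <- gb$dx
    dh_in <- gb$dh
    dalign <- rowSums(dC[cache$edge_dst, , drop = FALSE] * lc$Nsrc)
    dNsrc <- lc$align * dC[cache$edge_dst, , drop = FALSE]
    dlogit <- seg_softmax_backward(dalign, lc$align, gf_edge)
    dlogit_pre <- dlogit * lrelu_grad(lc$logit_pre, slope)
    dpa <- as.numeric(rowsum(dlogit_pre, gf_edge))
    dP <- outer(dpa, lp$a1)
    da1 <- colSums(lc$P * dpa)
    dNsrc <- dNsrc + outer(dlogit_pre, lp$a2)
    da2 <- colSums(lc$Nsrc * dlogit_pre)
    dh_in <- dh_in + dP %*% t(lp$Ws)
    dWs <- t(lc$h_in) %*% dP
    dHE <- dNsrc %*% t(lp$Wn)
    dWn <- t(lc$HE) %*% dNsrc
    dh_in <- dh_in + rowsum(dHE[, seq_len(D), drop = FALSE], gf_src)
    g$layers[[l]] <- list(Ws = dWs, Wn = dWn, a1 = da1, a2 = da2,
                          gru = gb$grads)
    dh <- dh_in
  }

  dh0_pre <- dh * lrelu_grad(cache$h0_pre, slope)
  g$W_in <- t(b$x) %*% dh0_pre
  g$b_in <- colSums(dh0_pre)
  g
}

#' Masked loss and its parameter gradients for one batch
#' @keywords internal
mt_loss_grad <- function(batch, labels, mask, model, training = TRUE) {
  fw <- mt_forward(batch, model, training = training, keep_cache = TRUE)
  n <- sum(mask)
  if (n == 0) stop("mask is all FALSE: no supervised signal")
  resid <- (fw$pred - labels) * mask
  loss <- sum(resid^2) / n
  dpred <- 2 * resid / n
  grads <- mt_backward(fw, dpred, model)
  list(loss = loss, grads = grads, pred = fw$pred)
}
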