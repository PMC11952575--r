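# Heterogeneous graph attention network for transcript-to-cell link
# prediction, implemented directly in base R matrix operations with
# hand-derived backpropagation (verified against finite differences in the
# test suite). Three directed relations are message-passed per layer, each
# with its own multi-head attention parameters:
#   tt: transcript -> transcript   (spatial neighbours)
#   ct: cell -> transcript         (candidate edges, reversed)
#   tc: transcript -> cell         (candidate edges)
# Attention logits are scaled dot products plus a learned per-head distance
# bias, so spatial proximity can inform routing even though node features
# carry no coordinates. Link score = sigmoid(z_t . z_c) on final latents.

elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
elu_grad_from_out <- function(out) ifelse(out > 0, 1, out + 1)
sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
}

# scatter rows of `vals` (grouped by integer `group`) into an n x d matrix
scatter_rowsum <- function(vals, group, n) {
  if (length(group) == 0) return(matrix(0, n, ncol(vals)))
  rs <- rowsum(vals, group)
  out <- matrix(0, n, ncol(vals))
  out[as.integer(rownames(rs)), ] <- rs
  out
}

group_max <- function(vals, group) {
  gm <- tapply(vals, group, max)
  as.numeric(gm[match(as.character(group), names(gm))])
}

# sample() without the length-1 numeric surprise
safe_sample <- function(x, n) x[sample.int(length(x), n)]

init_relation_par <- function(d, n_heads) {
  # distance bias starts negative so attention is distance-decaying from the
  # first epoch; training reshapes it per head
  list(Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d),
       Wo = glorot(d, d), bdist = rep(-1, n_heads))
}

# Flat named parameter list; names like "L1.tt.Wq" index layer/relation.
init_params <- function(d_in_t, d_in_c, cfg_model, learned_emb = NULL) {
  d <- cfg_model$d_latent
  par <- list(Wt = glorot(d_in_t, d), bt = rep(0, d),
              Wc = glorot(d_in_c, d), bc = rep(0, d))
  for (l in seq_len(cfg_model$n_layers)) {
    for (rel in c("tt", "ct", "tc")) {
      rp <- init_relation_par(d, cfg_model$n_heads)
      for (nm in names(rp)) par[[sprintf("L%d.%s.%s", l, rel, nm)]] <- rp[[nm]]
    }
  }
  if (!is.null(learned_emb)) par$emb <- learned_emb
  par
}

# ---- single-relation attention pass ---------------------------------------

amp_forward <- function(Hd, Hs, src, dst, dist, Wq, Wk, Wv, Wo, bdist,
                        n_heads, drop_p = 0, training = FALSE) {
  d <- ncol(Hd); dh <- d / n_heads
  nE <- length(src)
  if (nE == 0) {
    return(list(H = Hd, cache = list(empty = TRUE, Hd = Hd)))
  }
  Q <- Hd %*% Wq; K <- Hs %*% Wk; V <- Hs %*% Wv
  L <- matrix(0, nE, n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    L[, h] <- rowSums(Q[dst, idx, drop = FALSE] * K[src, idx, drop = FALSE]) /
      sqrt(dh) + bdist[h] * dist
  }
  rmax <- do.call(pmax, c(asplit(L, 2), list(na.rm = FALSE)))
  gm <- group_max(rmax, dst)
  expL <- exp(L - gm)
  ug <- sort(unique(dst))
  di <- match(dst, ug)
  denom <- rowsum(expL, dst)            # rows ordered by sort(unique(dst))
  A <- expL / denom[di, , drop = FALSE]
  O <- matrix(0, nrow(Hd), d)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    O[, idx] <- scatter_rowsum(A[, h] * V[src, idx, drop = FALSE], dst, nrow(Hd))
  }
  Y <- O %*% Wo
  mask <- NULL
  if (training && drop_p > 0) {
    mask <- matrix((runif(length(Y)) >= drop_p) / (1 - drop_p), nrow(Y), ncol(Y))
    Y <- Y * mask
  }
  has <- logical(nrow(Hd)); has[unique(dst)] <- TRUE
  H <- Hd
  H[has, ] <- elu(Hd[has, , drop = FALSE] + Y[has, , drop = FALSE])
  list(H = H,
       cache = list(empty = FALSE, Hd = Hd, Hs = Hs, Q = Q, K = K, V = V,
                    A = A, O = O, mask = mask, has = has, H = H,
                    src = src, dst = dst, dist = dist, di = di, ug = ug,
                    n_heads = n_heads, dh = dh))
}

amp_backward <- function(dH, cache, Wq, Wk, Wv, Wo) {
  if (cache$empty) {
    return(list(dHd = dH, dHs = matrix(0, 1, 1), dWq = NULL, dWk = NULL,
                dWv = NULL, dWo = NULL, dbdist = NULL, empty = TRUE))
  }
  with(cache, {
    d <- ncol(Hd)
    dHd <- matrix(0, nrow(Hd), d)
    dHs <- matrix(0, nrow(Hs), d)
    dHd[!has, ] <- dH[!has, , drop = FALSE]
    dpre <- matrix(0, nrow(Hd), d)
    dpre[has, ] <- dH[has, , drop = FALSE] *
      elu_grad_from_out(H[has, , drop = FALSE])
    dHd[has, ] <- dHd[has, , drop = FALSE] + dpre[has, , drop = FALSE]
    dY <- dpre
    if (!is.null(mask)) dY <- dY * mask
    dWo <- crossprod(O, dY)
    dO <- dY %*% t(Wo)
    dQ <- matrix(0, nrow(Hd), d)
    dK <- matrix(0, nrow(Hs), d)
    dV <- matrix(0, nrow(Hs), d)
    dbdist <- numeric(n_heads)
    for (h in seq_len(n_heads)) {
      idx <- ((h - 1) * dh + 1):(h * dh)
      dO_e <- dO[dst, idx, drop = FALSE]
      V_e <- V[src, idx, drop = FALSE]
      dA <- rowSums(dO_e * V_e)
      dV[, idx] <- dV[, idx, drop = FALSE] +
        scatter_rowsum(A[, h] * dO_e, src, nrow(Hs))
      s_grp <- rowsum(A[, h] * dA, dst)[di]
      dL <- A[, h] * (dA - s_grp)
      dbdist[h] <- sum(dL * dist)
      dQ[, idx] <- dQ[, idx, drop = FALSE] +
        scatter_rowsum((dL / sqrt(dh)) * K[src, idx, drop = FALSE], dst, nrow(Hd))
      dK[, idx] <- dK[, idx, drop = FALSE] +
        scatter_rowsum((dL / sqrt(dh)) * Q[dst, idx, drop = FALSE], src, nrow(Hs))
    }
    dWq <- crossprod(Hd, dQ)
    dWk <- crossprod(Hs, dK)
    dWv <- crossprod(Hs, dV)
    dHd <- dHd + dQ %*% t(Wq)
    dHs <- dHs + dK %*% t(Wk) + dV %*% t(Wv)
    list(dHd = dHd, dHs = dHs, dWq = dWq, dWk = dWk, dWv = dWv, dWo = dWo,
         dbdist = dbdist, empty = FALSE)
  })
}

#' One multi-head attention message-passing step over one edge type
#'
#' Destination states attend over incoming edges of a single relation:
#' per destination node and head, attention weights are nonnegative and sum
#' to one; the destination state becomes
#' `elu(state + concat(head outputs) %*% Wo)`. Nodes with no incoming edge
#' of this relation keep their state unchanged.
#'
#' @param dest_states,src_states node state matrices (rows = nodes).
#' @param src,dst integer edge endpoints (src indexes `src_states`, dst
#'   indexes `dest_states`).
#' @param dist edge distances (um) entering the learned per-head bias.
#' @param params relation parameters `list(Wq, Wk, Wv, Wo, bdist)`.
#' @param n_heads number of attention heads (must divide the state width).
#' @return Updated destination state matrix; attention weights (edges x
#'   heads) attached as attribute `"weights"`.
#' @export
attention_message_pass <- function(dest_states, src_states, src, dst,
                                   dist, params, n_heads) {
  r <- amp_forward(dest_states, src_states, src, dst, dist,
                   params$Wq, params$Wk, params$Wv, params$Wo, params$bdist,
                   n_heads)
  out <- r$H
  if (!r$cache$empty) attr(out, "weights") <- r$cache$A
  out
}

# ---- full forward / backward ----------------------------------------------

relation_par <- function(par, l, rel) {
  list(Wq = par[[sprintf("L%d.%s.Wq", l, rel)]],
       Wk = par[[sprintf("L%d.%s.Wk", l, rel)]],
       Wv = par[[sprintf("L%d.%s.Wv", l, rel)]],
       Wo = par[[sprintf("L%d.%s.Wo", l, rel)]],
       bdist = par[[sprintf("L%d.%s.bdist", l, rel)]])
}

forward_graph <- function(par, graph, cfg_model, training = FALSE) {
  drop_p <- if (training) cfg_model$dropout else 0
  x_t <- if (!is.null(par$emb)) {
    par$emb[graph$gene_index, , drop = FALSE]
  } else graph$x_t
  n_t <- length(graph$t_ids); n_c <- length(graph$c_ids)
  H_t <- sweep(x_t %*% par$Wt, 2, par$bt, "+")
  H_c <- if (n_c > 0) sweep(graph$x_c %*% par$Wc, 2, par$bc, "+") else
    matrix(0, 0, cfg_model$d_latent)
  caches <- vector("list", cfg_model$n_layers)
  for (l in seq_len(cfg_model$n_layers)) {
    p_tt <- relation_par(par, l, "tt")
    r1 <- amp_forward(H_t, H_t, graph$tt$j, graph$tt$i, graph$tt$dist,
                      p_tt$Wq, p_tt$Wk, p_tt$Wv, p_tt$Wo, p_tt$bdist,
                      cfg_model$n_heads, drop_p, training)
    p_ct <- relation_par(par, l, "ct")
    r2 <- amp_forward(r1$H, H_c, graph$tc$c, graph$tc$t, graph$tc$dist,
                      p_ct$Wq, p_ct$Wk, p_ct$Wv, p_ct$Wo, p_ct$bdist,
                      cfg_model$n_heads, drop_p, training)
    p_tc <- relation_par(par, l, "tc")
    r3 <- amp_forward(H_c, r2$H, graph$tc$t, graph$tc$c, graph$tc$dist,
                      p_tc$Wq, p_tc$Wk, p_tc$Wv, p_tc$Wo, p_tc$bdist,
                      cfg_model$n_heads, drop_p, training)
    H_t <- r2$H; H_c <- r3$H
    caches[[l]] <- list(r1 = r1$cache, r2 = r2$cache, r3 = r3$cache)
  }
  list(z_t = H_t, z_c = H_c, caches = caches, x_t = x_t)
}

backward_graph <- function(par, graph, cfg_model, fwd, dz_t, dz_c) {
  grads <- list()
  add_rel <- function(l, rel, b) {
    if (isTRUE(b$empty)) return()
    for (nm in c("Wq", "Wk", "Wv", "Wo", "bdist")) {
      key <- sprintf("L%d.%s.%s", l, rel, nm)
      g <- b[[paste0("d", nm)]]
      grads[[key]] <<- if (is.null(grads[[key]])) g else grads[[key]] + g
    }
  }
  for (l in rev(seq_len(cfg_model$n_layers))) {
    cc <- fwd$caches[[l]]
    p_tc <- relation_par(par, l, "tc")
    b3 <- amp_backward(dz_c, cc$r3, p_tc$Wq, p_tc$Wk, p_tc$Wv, p_tc$Wo)
    add_rel(l, "tc", b3)
    dz_c <- b3$dHd
    dz_t <- dz_t + (if (isTRUE(b3$empty)) 0 else b3$dHs)
    p_ct <- relation_par(par, l, "ct")
    b2 <- amp_backward(dz_t, cc$r2, p_ct$Wq, p_ct$Wk, p_ct$Wv, p_ct$Wo)
    add_rel(l, "ct", b2)
    dz_t <- b2$dHd
    dz_c <- dz_c + (if (isTRUE(b2$empty)) 0 else b2$dHs)
    p_tt <- relation_par(par, l, "tt")
    b1 <- amp_backward(dz_t, cc$r1, p_tt$Wq, p_tt$Wk, p_tt$Wv, p_tt$Wo)
    add_rel(l, "tt", b1)
    dz_t <- b1$dHd + (if (isTRUE(b1$empty)) 0 else b1$dHs)
  }
  grads$Wt <- crossprod(fwd$x_t, dz_t)
  grads$bt <- colSums(dz_t)
  if (length(graph$c_ids) > 0) {
    grads$Wc <- crossprod(graph$x_c, dz_c)
    grads$bc <- colSums(dz_c)
  }
  if (!is.null(par$emb)) {
    dx_t <- dz_t %*% t(par$Wt)
    grads$emb <- scatter_rowsum(dx_t, graph$gene_index, nrow(par$emb))
  }
  grads
}

#' Link score from latent vectors
#'
#' The probability that a transcript and a cell are associated is the
#' sigmoid of the dot product of their latent vectors, so proximity in the
#' joint latent space maps monotonically to association probability.
#'
#' @param z_t,z_c latent vectors (or matrices of matching rows).
#' @return Probabilities in (0, 1).
#' @export
score_link <- function(z_t, z_c) {
  if (is.matrix(z_t)) sigmoid(rowSums(z_t * z_c)) else sigmoid(sum(z_t * z_c))
}

# BCE loss + gradient on a set of scored edges
bce_and_grads <- function(fwd, graph, edge_idx, y) {
  t_i <- graph$tc$t[edge_idx]; c_i <- graph$tc$c[edge_idx]
  s <- rowSums(fwd$z_t[t_i, , drop = FALSE] * fwd$z_c[c_i, , drop = FALSE])
  p <- sigmoid(s)
  eps <- 1e-12
  loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  g <- (p - y) / length(y)
  dz_t <- scatter_rowsum(g * fwd$z_c[c_i, , drop = FALSE], t_i, nrow(fwd$z_t))
  dz_c <- scatter_rowsum(g * fwd$z_t[t_i, , drop = FALSE], c_i, nrow(fwd$z_c))
  list(loss = loss, dz_t = dz_t, dz_c = dz_c, p = p)
}

adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0; state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

auroc <- function(scores, labels) {
  if (length(unique(labels)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

# Split labeled edges into train / validation. With >= 5 graphs, whole
# tiles are held out; otherwise 10% of positive-labeled transcripts (with
# all their labeled edges) per graph.
make_split <- function(graphs, val_fraction) {
  n <- length(graphs)
  split <- vector("list", n)
  if (n >= 5) {
    n_val <- max(1, round(val_fraction * n))
    val_tiles <- sample(n, n_val)
    for (k in seq_len(n)) {
      lab <- which(graphs[[k]]$tc$label != "unlabeled")
      if (k %in% val_tiles) {
        split[[k]] <- list(train = integer(0), val = lab)
      } else {
        split[[k]] <- list(train = lab, val = integer(0))
      }
    }
  } else {
    for (k in seq_len(n)) {
      tc <- graphs[[k]]$tc
      pos_t <- unique(tc$t[tc$label == "positive"])
      n_val <- max(1, round(val_fraction * length(pos_t)))
      val_t <- if (length(pos_t)) safe_sample(pos_t, min(n_val, length(pos_t))) else integer(0)
      lab <- which(tc$label != "unlabeled")
      is_val <- tc$t[lab] %in% val_t
      split[[k]] <- list(train = lab[!is_val], val = lab[is_val])
    }
  }
  split
}

#' Train the link-prediction model
#'
#' Minimizes binary cross-entropy over labeled candidate transcript-cell
#' edges (nucleus-overlap positives vs neighbouring-nucleus negatives) with
#' Adam, subsampling negatives to `neg_per_pos` per positive each epoch.
#' Unlabeled edges never enter the loss. A held-out fraction (whole tiles
#' when many are available, otherwise 10% of positive-labeled transcripts)
#' reports validation AUROC per epoch, and the parameters of the best
#' validation epoch are returned. Fully deterministic under `cfg$model$seed`.
#'
#' @param graphs list of `hetero_graph` tiles from [build_tile_graph()].
#' @param cfg configuration ([linkseg_config()]); `cfg$model` holds
#'   `d_latent`, `n_layers`, `n_heads`, `dropout`, `lr`, `epochs`,
#'   `neg_per_pos`, `val_fraction`, `seed`.
#' @param embedding the `gene_embedding` used to build the graphs; when its
#'   mode is `"learned"` the table is trained as a parameter.
#' @param verbose print per-epoch loss and validation AUROC.
#' @return A `trained_model`: parameters, config, gene vocabulary,
#'   embedding, feature-standardization statistics, training history.
#' @export
train_model <- function(graphs, cfg = linkseg_config(), embedding,
                        verbose = FALSE) {
  cm <- cfg$model
  stopifnot(cm$d_latent %% cm$n_heads == 0, cm$epochs >= 1, cm$neg_per_pos >= 1)
  n_pos_total <- sum(vapply(graphs, function(g) sum(g$tc$label == "positive"), 0))
  if (n_pos_total == 0) {
    stop("training error: no positive transcript-cell edges; ",
         "check that nuclei overlap transcripts and labels were computed")
  }
  with_seed(cm$seed, {
    learned <- if (identical(embedding$mode, "learned")) embedding$vectors else NULL
    par <- init_params(embedding$d, ncol(graphs[[1]]$x_c), cm, learned)
    split <- make_split(graphs, cm$val_fraction)
    state <- list(t = 0, m = list(), v = list())
    history <- data.frame(epoch = integer(0), loss = numeric(0),
                          val_auroc = numeric(0))
    best <- list(auroc = -Inf, par = par, epoch = 0)
    for (ep in seq_len(cm$epochs)) {
      ep_loss <- 0; n_batches <- 0
      for (k in seq_along(graphs)) {
        g <- graphs[[k]]
        tr <- split[[k]]$train
        if (length(tr) == 0) next
        lab <- g$tc$label[tr]
        pos <- tr[lab == "positive"]; neg <- tr[lab == "negative"]
        if (length(pos) == 0) next
        # maintain the neg_per_pos class ratio in the loss: subsample when
        # negatives abound, resample when the graph offers fewer
        take <- cm$neg_per_pos * length(pos)
        neg_s <- if (length(neg) > 0) {
          neg[sample.int(length(neg), take, replace = length(neg) < take)]
        } else integer(0)
        sel <- c(pos, neg_s)
        y <- c(rep(1, length(pos)), rep(0, length(neg_s)))
        fwd <- forward_graph(par, g, cm, training = TRUE)
        bl <- bce_and_grads(fwd, g, sel, y)
        grads <- backward_graph(par, g, cm, fwd, bl$dz_t, bl$dz_c)
        st <- adam_step(par, grads, state, cm$lr)
        par <- st$par; state <- st$state
        ep_loss <- ep_loss + bl$loss; n_batches <- n_batches + 1
      }
      # validation AUROC in eval mode
      vs <- numeric(0); vy <- numeric(0)
      for (k in seq_along(graphs)) {
        va <- split[[k]]$val
        if (length(va) == 0) next
        fwd <- forward_graph(par, graphs[[k]], cm, training = FALSE)
        t_i <- graphs[[k]]$tc$t[va]; c_i <- graphs[[k]]$tc$c[va]
        vs <- c(vs, sigmoid(rowSums(fwd$z_t[t_i, , drop = FALSE] *
                                    fwd$z_c[c_i, , drop = FALSE])))
        vy <- c(vy, as.numeric(graphs[[k]]$tc$label[va] == "positive"))
      }
      va_auc <- auroc(vs, vy)
      history <- rbind(history, data.frame(
        epoch = ep, loss = ep_loss / max(n_batches, 1), val_auroc = va_auc))
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f val AUROC %.4f", ep,
                        ep_loss / max(n_batches, 1), va_auc))
      }
      if (!is.na(va_auc) && va_auc > best$auroc) {
        best <- list(auroc = va_auc, par = par, epoch = ep)
      }
    }
    final_par <- if (is.finite(best$auroc)) best$par else par
    emb_out <- embedding
    if (!is.null(final_par$emb)) {
      emb_out$vectors <- final_par$emb
      rownames(emb_out$vectors) <- emb_out$genes
    }
    structure(list(par = final_par, config = cfg, genes = embedding$genes,
                   embedding = emb_out,
                   feat_stats = graphs[[1]]$feat_stats,
                   history = history, best_epoch = best$epoch,
                   val_auroc = best$auroc,
                   model_id = rlang::hash(list(cfg$model, embedding$mode))),
              class = "trained_model")
  })
}

#' Score all candidate edges of a graph
#'
#' Runs the model in evaluation mode (dropout off; deterministic) and
#' returns a probability for every candidate transcript-cell edge, labeled
#' or not.
#'
#' @param model a `trained_model`.
#' @param graph a `hetero_graph` built with the model's vocabulary and
#'   feature statistics.
#' @return data.frame `transcript_id, cell_id, dist, label, score`; final
#'   transcript latents attached as attribute `"z_t"` (rows named by
#'   transcript id).
#' @export
predict_scores <- function(model, graph) {
  if (!identical(model$genes, model$embedding$genes)) {
    stop("model vocabulary is inconsistent")
  }
  if (any(!is.na(graph$gene_index) & graph$gene_index > length(model$genes))) {
    stop("vocabulary mismatch between graph and model")
  }
  fwd <- forward_graph(model$par, graph, model$config$model, training = FALSE)
  tc <- graph$tc
  s <- if (nrow(tc)) {
    sigmoid(rowSums(fwd$z_t[tc$t, , drop = FALSE] *
                    fwd$z_c[tc$c, , drop = FALSE]))
  } else numeric(0)
  out <- data.frame(transcript_id = graph$t_ids[tc$t],
                    cell_id = graph$c_ids[tc$c],
                    dist = tc$dist, label = tc$label, score = s,
                    stringsAsFactors = FALSE)
  zt <- fwd$z_t
  rownames(zt) <- graph$t_ids
  attr(out, "z_t") <- zt
  out
}

#' Serialize a trained model to a plain-text archive
#'
#' Writes a single JSON file holding parameters, config, vocabulary,
#' standardization statistics and a format version.
#'
#' @param model a `trained_model`.
#' @param path output `.json` path.
#' @export
write_model <- function(model, path) {
  pl <- lapply(model$par, function(p) {
    if (is.matrix(p)) list(dim = dim(p), x = as.numeric(p)) else
      list(dim = NULL, x = as.numeric(p))
  })
  obj <- list(format_version = 1L, par = pl, config = model$config,
              genes = model$genes,
              embedding = list(genes = model$embedding$genes,
                               vectors = as.numeric(model$embedding$vectors),
                               d = model$embedding$d,
                               mode = model$embedding$mode),
              feat_stats = model$feat_stats, model_id = model$model_id)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a model archive written by [write_model()]
#' @param path `.json` path.
#' @return A `trained_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  par <- lapply(obj$par, function(p) {
    dims <- unlist(p$dim); x <- as.numeric(unlist(p$x))
    if (length(dims) == 2) matrix(x, dims[1], dims[2]) else x
  })
  emb <- new_gene_embedding(unlist(obj$embedding$genes),
                            matrix(as.numeric(unlist(obj$embedding$vectors)),
                                   length(unlist(obj$embedding$genes)),
                                   obj$embedding$d),
                            obj$embedding$mode)
  cfg <- linkseg_config(rapply(obj$config, identity, how = "list"))
  fs <- list(mean = unlist(obj$feat_stats$mean), sd = unlist(obj$feat_stats$sd))
  structure(list(par = par, config = cfg, genes = obj$genes, embedding = emb,
                 feat_stats = fs, history = NULL, best_epoch = NA,
                 val_auroc = NA, model_id = obj$model_id),
            class = "trained_model")
}
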