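#' @include AllGenerics.R
NULL

# Compact native recurrent regressors (stacked Elman RNN / LSTM) for the
# two-step ED/ES feature sequence: a stack of recurrent layers followed
# by a single dense output unit, trained on mean squared error by
# backpropagation through time with SGD or Adam.  Written in plain
# matrix algebra; with sequence length 2 and a few thousand weights this
# is fast and fully deterministic given the seed.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nin, nout) {
    lim <- sqrt(6 / (nin + nout))
    matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

initNet <- function(kind, inputDim, units) {
    gates <- if (kind == "lstm") 4L else 1L
    layers <- vector("list", length(units))
    din <- inputDim
    for (j in seq_along(units)) {
        u <- units[j]
        W <- do.call(cbind, replicate(gates, glorot(din, u),
                                      simplify = FALSE))
        U <- do.call(cbind, replicate(gates, glorot(u, u),
                                      simplify = FALSE))
        b <- numeric(gates * u)
        if (kind == "lstm") b[u + seq_len(u)] <- 1   # forget-gate bias
        layers[[j]] <- list(W = W, U = U, b = b, units = u)
        din <- u
    }
    list(kind = kind, layers = layers,
         Wo = glorot(units[length(units)], 1L), bo = 0)
}

forwardPass <- function(net, Xarr) {
    B <- dim(Xarr)[1]; Tn <- dim(Xarr)[2]
    inp <- lapply(seq_len(Tn), function(t)
        matrix(Xarr[, t, ], nrow = B))
    caches <- vector("list", length(net$layers))
    for (j in seq_along(net$layers)) {
        ly <- net$layers[[j]]
        u <- ly$units
        hprev <- matrix(0, B, u)
        cprev <- matrix(0, B, u)
        hs <- vector("list", Tn)
        cache <- vector("list", Tn)
        for (t in seq_len(Tn)) {
            z <- sweep(inp[[t]] %*% ly$W + hprev %*% ly$U, 2, ly$b, "+")
            if (net$kind == "rnn") {
                h <- tanh(z)
                cache[[t]] <- list(x = inp[[t]], hprev = hprev, h = h)
            } else {
                ig <- sigmoid(z[, seq_len(u), drop = FALSE])
                fg <- sigmoid(z[, u + seq_len(u), drop = FALSE])
                og <- sigmoid(z[, 2 * u + seq_len(u), drop = FALSE])
                gg <- tanh(z[, 3 * u + seq_len(u), drop = FALSE])
                cc <- fg * cprev + ig * gg
                tc <- tanh(cc)
                h <- og * tc
                cache[[t]] <- list(x = inp[[t]], hprev = hprev,
                                   cprev = cprev, i = ig, f = fg, o = og,
                                   g = gg, tc = tc, h = h)
                cprev <- cc
            }
            hprev <- h
            hs[[t]] <- h
        }
        caches[[j]] <- cache
        inp <- hs
    }
    yhat <- as.numeric(inp[[Tn]] %*% net$Wo + net$bo)
    list(yhat = yhat, caches = caches)
}

zeroLike <- function(net) {
    list(layers = lapply(net$layers, function(ly)
            list(W = ly$W * 0, U = ly$U * 0, b = ly$b * 0)),
         Wo = net$Wo * 0, bo = 0)
}

backwardPass <- function(net, fw, dy) {
    B <- length(dy)
    Tn <- length(fw$caches[[1]])
    J <- length(net$layers)
    g <- zeroLike(net)
    hLast <- fw$caches[[J]][[Tn]]$h
    g$Wo <- crossprod(hLast, matrix(dy, ncol = 1))
    g$bo <- sum(dy)
    Gh <- lapply(net$layers, function(ly)
        lapply(seq_len(Tn), function(t) matrix(0, B, ly$units)))
    Gc <- lapply(net$layers, function(ly) matrix(0, B, ly$units))
    Gh[[J]][[Tn]] <- matrix(dy, ncol = 1) %*% t(net$Wo)
    for (t in rev(seq_len(Tn))) {
        for (j in rev(seq_len(J))) {
            ly <- net$layers[[j]]
            ca <- fw$caches[[j]][[t]]
            gh <- Gh[[j]][[t]]
            if (net$kind == "rnn") {
                gz <- gh * (1 - ca$h^2)
            } else {
                dct <- Gc[[j]] + gh * ca$o * (1 - ca$tc^2)
                gz <- cbind(
                    (dct * ca$g) * ca$i * (1 - ca$i),
                    (dct * ca$cprev) * ca$f * (1 - ca$f),
                    (gh * ca$tc) * ca$o * (1 - ca$o),
                    (dct * ca$i) * (1 - ca$g^2))
                Gc[[j]] <- dct * ca$f
            }
            g$layers[[j]]$W <- g$layers[[j]]$W + crossprod(ca$x, gz)
            g$layers[[j]]$U <- g$layers[[j]]$U + crossprod(ca$hprev, gz)
            g$layers[[j]]$b <- g$layers[[j]]$b + colSums(gz)
            if (t > 1L)
                Gh[[j]][[t - 1L]] <- Gh[[j]][[t - 1L]] + gz %*% t(ly$U)
            if (j > 1L)
                Gh[[j - 1L]][[t]] <- Gh[[j - 1L]][[t]] + gz %*% t(ly$W)
        }
    }
    g
}

# Parameter update; state carries Adam moments and the step counter.
applyUpdate <- function(net, g, state, lr, optimizer) {
    if (optimizer == "sgd") {
        for (j in seq_along(net$layers))
            for (nm in c("W", "U", "b"))
                net$layers[[j]][[nm]] <-
                    net$layers[[j]][[nm]] - lr * g$layers[[j]][[nm]]
        net$Wo <- net$Wo - lr * g$Wo
        net$bo <- net$bo - lr * g$bo
        return(list(net = net, state = state))
    }
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    state$t <- state$t + 1L
    upd <- function(p, grad, key) {
        m <- b1 * state$m[[key]] + (1 - b1) * grad
        v <- b2 * state$v[[key]] + (1 - b2) * grad^2
        state$m[[key]] <<- m
        state$v[[key]] <<- v
        mh <- m / (1 - b1^state$t)
        vh <- v / (1 - b2^state$t)
        p - lr * mh / (sqrt(vh) + eps)
    }
    for (j in seq_along(net$layers))
        for (nm in c("W", "U", "b")) {
            key <- paste0("l", j, nm)
            net$layers[[j]][[nm]] <-
                upd(net$layers[[j]][[nm]], g$layers[[j]][[nm]], key)
        }
    net$Wo <- upd(net$Wo, g$Wo, "Wo")
    net$bo <- upd(net$bo, g$bo, "bo")
    list(net = net, state = state)
}

initAdamState <- function(net) {
    zeros <- list()
    for (j in seq_along(net$layers))
        for (nm in c("W", "U", "b"))
            zeros[[paste0("l", j, nm)]] <- net$layers[[j]][[nm]] * 0
    zeros$Wo <- net$Wo * 0
    zeros$bo <- 0
    list(m = zeros, v = zeros, t = 0L)
}

trainRecurrent <- function(Xarr, y, kind = c("rnn", "lstm"),
                           units = c(32L, 16L), lr = 0.001,
                           epochs = 70L, batchSize = 32L,
                           optimizer = c("adam", "sgd"), seed = 1L) {
    kind <- match.arg(kind)
    optimizer <- match.arg(optimizer)
    n <- dim(Xarr)[1]
    withSeed(seed, {
        net <- initNet(kind, dim(Xarr)[3], as.integer(units))
        state <- initAdamState(net)
        for (ep in seq_len(epochs)) {
            ord <- sample(n)
            for (s in seq(1L, n, by = batchSize)) {
                idx <- ord[s:min(s + batchSize - 1L, n)]
                Xb <- Xarr[idx, , , drop = FALSE]
                fw <- forwardPass(net, Xb)
                dy <- 2 * (fw$yhat - y[idx]) / length(idx)
                g <- backwardPass(net, fw, dy)
                res <- applyUpdate(net, g, state, lr, optimizer)
                net <- res$net
                state <- res$state
            }
        }
        net
    })
}

predictRecurrent <- function(net, Xarr) {
    forwardPass(net, Xarr)$yhat
}
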