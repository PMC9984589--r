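#' Construct an AffineTransform
#'
#' @param matrix 3x3 numeric matrix A.
#' @param translation length-3 numeric vector t (mm).
#' @return an [AffineTransform-class] mapping p to A p + t.
#' @export
affineTransform <- function(matrix, translation = c(0, 0, 0)) {
    m <- base::matrix(as.numeric(matrix), 3L, 3L)
    new("AffineTransform", matrix = m,
        translation = as.numeric(translation))
}

#' Pair two landmark sets by name
#'
#' Correspondence is established by landmark name, not file order, so source
#' and target files may list landmarks differently. Only names present in
#' both sets are used.
#'
#' @param source,target [LandmarkSet-class] objects.
#' @return a list with matrices \code{source}, \code{target} (n x 3, same
#'   row order) and \code{names}.
#' @export
pairLandmarks <- function(source, target) {
    common <- intersect(source@names, target@names)
    if (length(common) < 4L)
        stop("need at least 4 common landmarks, found ", length(common))
    list(source = source@coords[match(common, source@names), , drop = FALSE],
         target = target@coords[match(common, target@names), , drop = FALSE],
         names = common)
}

.check_not_coplanar <- function(src, what = "source") {
    ctr <- sweep(src, 2L, colMeans(src))
    sv <- svd(ctr)$d
    ratio <- sv[3L] / sv[1L]
    if (!is.finite(ratio) || ratio <= 1e-9)
        stop("degenerate landmark configuration: ", what,
             " points are coplanar or collinear ",
             sprintf("(singular-value ratio %.3e <= 1e-9)", ratio))
    invisible(ratio)
}

#' Fit an affine transform to corresponding landmark pairs
#'
#' Least-squares 12-DOF affine minimizing \eqn{\sum_i \|A s_i + t - t_i\|^2},
#' solved through the SVD pseudoinverse of the homogeneous design matrix.
#' This is the morphing step that registers the atlas bony landmarks onto
#' the subject landmarks; the fitted map is then applied to the atlas muscle
#' origin/insertion points. The fit is exact (zero residual) whenever the
#' targets are an exact affine image of the sources.
#'
#' @param source,target [LandmarkSet-class] objects (paired by name), or
#'   n x 3 matrices in matching row order. At least 4 non-coplanar pairs are
#'   required.
#' @return an [AffineTransform-class]; attribute \code{rms} carries the
#'   root-mean-square fit residual in mm.
#' @examples
#' src <- matrix(rnorm(36), 12, 3)
#' tr <- affineTransform(diag(3) * 1.1, c(5, 0, 0))
#' fit <- fitAffine(src, applyTransform(tr, src))
#' attr(fit, "rms")  # ~0
#' @export
fitAffine <- function(source, target) {
    if (is(source, "LandmarkSet")) {
        pr <- pairLandmarks(source, target)
        src <- pr$source; tgt <- pr$target
    } else {
        src <- as.matrix(source); tgt <- as.matrix(target)
    }
    if (nrow(src) < 4L)
        stop("affine fitting needs at least 4 landmark pairs, got ",
             nrow(src))
    if (!identical(dim(src), dim(tgt)))
        stop("source and target landmark counts differ")
    .check_not_coplanar(src)
    X <- cbind(src, 1)             # n x 4 homogeneous design
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-12
    pinv <- sv$v[, pos, drop = FALSE] %*%
        (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    beta <- pinv %*% tgt           # 4 x 3, rows: A columns + translation
    A <- t(beta[1:3, , drop = FALSE])
    tvec <- as.numeric(beta[4L, ])
    fit <- affineTransform(A, tvec)
    res <- X %*% beta - tgt
    attr(fit, "rms") <- sqrt(mean(rowSums(res^2)))
    fit
}

#' Fit a similarity transform (rotation + isotropic scale + translation)
#'
#' Umeyama closed-form solution; provided as a sensitivity alternative to
#' the full 12-DOF affine of [fitAffine()] when a rigid-plus-scale morph is
#' preferred.
#'
#' @inheritParams fitAffine
#' @return an [AffineTransform-class] whose matrix is s R, with attribute
#'   \code{rms}.
#' @export
fitSimilarity <- function(source, target) {
    if (is(source, "LandmarkSet")) {
        pr <- pairLandmarks(source, target)
        src <- pr$source; tgt <- pr$target
    } else {
        src <- as.matrix(source); tgt <- as.matrix(target)
    }
    if (nrow(src) < 4L)
        stop("similarity fitting needs at least 4 landmark pairs")
    .check_not_coplanar(src)
    mu_s <- colMeans(src); mu_t <- colMeans(tgt)
    cs <- sweep(src, 2L, mu_s); ct <- sweep(tgt, 2L, mu_t)
    S <- t(ct) %*% cs / nrow(src)
    sv <- svd(S)
    D <- diag(3)
    if (det(sv$u) * det(sv$v) < 0) D[3L, 3L] <- -1
    R <- sv$u %*% D %*% t(sv$v)
    var_s <- mean(rowSums(cs^2))
    scale <- sum(sv$d * diag(D)) / var_s
    A <- scale * R
    tvec <- mu_t - as.numeric(A %*% mu_s)
    fit <- affineTransform(A, tvec)
    res <- sweep(src %*% t(A), 2L, tvec, `+`) - tgt
    attr(fit, "rms") <- sqrt(mean(rowSums(res^2)))
    fit
}

#' Invert an affine transform
#'
#' @param transform an [AffineTransform-class].
#' @return the inverse [AffineTransform-class].
#' @export
invertTransform <- function(transform) {
    Ai <- solve(transform@matrix)
    affineTransform(Ai, -as.numeric(Ai %*% transform@translation))
}

#' @rdname applyTransform
setMethod("applyTransform", signature("AffineTransform", "LandmarkSet"),
          function(transform, points) {
    landmarkSet(points@names,
                applyTransform(transform, points@coords))
})

#' @rdname applyTransform
setMethod("applyTransform", signature("AffineTransform", "matrix"),
          function(transform, points) {
    sweep(points %*% t(transform@matrix), 2L, transform@translation, `+`)
})

#' @rdname applyTransform
setMethod("applyTransform", signature("AffineTransform", "numeric"),
          function(transform, points) {
    as.numeric(transform@matrix %*% points + transform@translation)
})

# closest point on each triangle to p (Ericson-style region tests),
# vectorized over triangles; returns n_faces x 3 matrix
.closest_on_triangles <- function(p, v, f) {
    a <- v[f[, 1L], , drop = FALSE]
    b <- v[f[, 2L], , drop = FALSE]
    c_ <- v[f[, 3L], , drop = FALSE]
    ab <- b - a; ac <- c_ - a
    ap <- matrix(p, nrow(a), 3L, byrow = TRUE) - a
    d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
    bp <- matrix(p, nrow(a), 3L, byrow = TRUE) - b
    d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
    cp <- matrix(p, nrow(a), 3L, byrow = TRUE) - c_
    d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
    va <- d3 * d6 - d5 * d4
    vb <- d5 * d2 - d1 * d6
    vc <- d1 * d4 - d3 * d2
    out <- matrix(NA_real_, nrow(a), 3L)
    done <- rep(FALSE, nrow(a))
    setrows <- function(idx, m) {
        fresh <- idx & !done
        out[fresh, ] <<- m[fresh, , drop = FALSE]
        done <<- done | idx
    }
    setrows(d1 <= 0 & d2 <= 0, a)                                  # vertex a
    setrows(d3 >= 0 & d4 <= d3, b)                                 # vertex b
    setrows(d6 >= 0 & d5 <= d6, c_)                                # vertex c
    wab <- ifelse(abs(d1 - d3) > 0, d1 / (d1 - d3), 0)
    setrows(vc <= 0 & d1 >= 0 & d3 <= 0, a + wab * ab)             # edge ab
    wac <- ifelse(abs(d2 - d6) > 0, d2 / (d2 - d6), 0)
    setrows(vb <= 0 & d2 >= 0 & d6 <= 0, a + wac * ac)             # edge ac
    wbc <- ifelse(abs((d4 - d3) + (d5 - d6)) > 0,
                  (d4 - d3) / ((d4 - d3) + (d5 - d6)), 0)
    setrows(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0,
            b + wbc * (c_ - b))                                    # edge bc
    denom <- va + vb + vc
    denom[denom == 0] <- 1
    out[!done, ] <- (a + (vb / denom) * ab +
                         (vc / denom) * ac)[!done, , drop = FALSE] # interior
    out
}

#' Snap a point to the nearest point on a bone surface
#'
#' Relocates an attachment point to the nearest point on the continuous mesh
#' surface (triangle interiors and edges, not just vertices), emulating the
#' correction applied when a morphed muscle attachment does not lie on the
#' bone. If the nearest surface point is farther than \code{max_snap_mm},
#' the input is returned unchanged with a warning — the automated analogue
#' of flagging the point for a visual check.
#'
#' @param point length-3 world-mm point.
#' @param surface a [SurfaceMesh-class].
#' @param max_snap_mm maximum allowed snap displacement (mm); default 15.
#' @return the (possibly moved) point, with attributes \code{snapped}
#'   (logical) and \code{distance} (mm).
#' @export
snapToSurface <- function(point, surface, max_snap_mm = 15) {
    stopifnot(is(surface, "SurfaceMesh"), max_snap_mm > 0)
    if (nrow(surface@faces) == 0L)
        stop("cannot snap to an empty mesh")
    cand <- .closest_on_triangles(as.numeric(point), surface@vertices,
                                  surface@faces)
    d2 <- rowSums(sweep(cand, 2L, as.numeric(point))^2)
    i <- which.min(d2)
    d <- sqrt(d2[i])
    if (d > max_snap_mm) {
        warning(sprintf(
            "nearest surface point is %.2f mm away (> max_snap_mm = %.2f); point left unchanged",
            d, max_snap_mm))
        out <- as.numeric(point)
        attr(out, "snapped") <- FALSE
        attr(out, "distance") <- d
        return(out)
    }
    out <- as.numeric(cand[i, ])
    attr(out, "snapped") <- d > 1e-9
    attr(out, "distance") <- d
    out
}

#' Serialize / deserialize an AffineTransform to JSON
#'
#' @param transform an [AffineTransform-class].
#' @param path JSON file path.
#' @return \code{readTransform} returns the [AffineTransform-class].
#' @export
writeTransform <- function(transform, path) {
    jsonlite::write_json(
        list(matrix = as.numeric(t(transform@matrix)),  # row-major
             translation = transform@translation),
        path, digits = I(17))
    invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    affineTransform(matrix(x$matrix, 3L, 3L, byrow = TRUE), x$translation)
}
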