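# Deterministic substream seeds: one global seed expands into independent
# per-(repeat, slice) substreams by fixed integer hashing. All arithmetic
# stays exact in doubles and the result stays below 2^31.
substreamSeed <- function(seed, a = 0L, b = 0L) {
    s <- as.numeric(seed) %% 100003
    as.integer((s * 30011 + as.numeric(a) * 1009 +
                    as.numeric(b) * 101 + 17) %% 2147483563)
}

# Evaluate expr under a fixed seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

# axis-aligned box as a closed triangle mesh (12 faces, outward normals)
.box_mesh <- function(lo, hi) {
    v <- as.matrix(expand.grid(x = c(lo[1L], hi[1L]),
                               y = c(lo[2L], hi[2L]),
                               z = c(lo[3L], hi[3L])))
    # vertex order from expand.grid: x fastest; index = 1 + ix + 2*iy + 4*iz
    f <- rbind(
        c(1, 3, 7), c(1, 7, 5),   # x = lo
        c(2, 8, 4), c(2, 6, 8),   # x = hi
        c(1, 6, 2), c(1, 5, 6),   # y = lo
        c(3, 4, 8), c(3, 8, 7),   # y = hi
        c(1, 2, 4), c(1, 4, 3),   # z = lo
        c(5, 8, 6), c(5, 7, 8))   # z = hi
    surfaceMesh(v, f)
}

# merge meshes into one (no vertex welding needed for disjoint solids)
.merge_meshes <- function(a, b) {
    surfaceMesh(rbind(a@vertices, b@vertices),
                rbind(a@faces, b@faces + nrow(a@vertices)))
}
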