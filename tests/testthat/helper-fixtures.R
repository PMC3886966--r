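# shared fixtures, all generated in code

tinyObsCsv <- function(path = tempfile(fileext = ".csv")) {
    writeLines(c("animal_id,maternal,diet,time_h,gene,value",
                 "a1,lean,control,6,PPARA,1.0",
                 "a2,lean,control,10,PPARA,1.4"), path)
    path
}

# a well-behaved group-mean curve built directly (not via groupMeans)
makeCurve <- function(times = c(2, 6, 10, 14, 18, 22),
                      means = c(0.9, 1.0, 1.8, 1.5, 1.1, 0.8),
                      sems = rep(0.05, length(times)),
                      ns = rep(4L, length(times)),
                      gene = "BMAL1", maternal = "lean", diet = "control") {
    o <- order(times)
    methods::new("GroupMeanCurve", gene = gene, maternal = maternal,
                 diet = diet, times = times[o], means = means[o],
                 sems = sems[o], ns = as.integer(ns[o]))
}

# curve whose means are the model's own entrained solution at the six
# sampling hours (noiseless closed loop)
modelCurve <- function(params, forcing, times = c(6, 10, 14, 18, 22, 2),
                       sems = rep(0.02, 6)) {
    tr <- periodicSolution(params, forcing, dt = 0.25, tol = 1e-8)
    tu <- unwrapTimes(times)
    mu <- stats::approx(tr@times, tr@values, xout = sort(tu))$y
    makeCurve(times = sort(tu) %% 24, means = mu, sems = sems,
              gene = "PPARA")
}
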