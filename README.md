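# phikinet

Quantitative photokinetics for unimolecular photoreactions driven by
monochromatic light — simulation, Φ-order trace fitting, quantum-yield and
absorption-coefficient recovery, and actinometry — for photochemists and
drug-photostability researchers who need more than first-order
approximations.

## The science in brief

Under continuous monochromatic irradiation in a well-stirred slab reactor,
every photoreaction step `Yj -> Yj'` proceeds at a rate proportional to the
photon flux its reagent absorbs:

    r_j(t) = Σ_{j'≠j} [ −Φ_{j→j'} · Pa_j(t) + Φ_{j'→j} · Pa_j'(t) ]
    Pa_j(t) = A_j(t) · P0 · (1 − 10^(−Atot(t))) / Atot(t)

with `A_j = ε_j l C_j`, `Atot` the total absorbance of the medium (including
inert absorbing spectators), `P0` the incident photon flux (einstein s⁻¹
dm⁻³) and `Φ` the quantum yields. The photokinetic factor
`(1 − 10^(−Atot))/Atot` makes the system nonlinear; no closed-form solution
exists except for the primary photoprocess with a transparent product.

The package integrates this rate law with fixed-step fourth-order
Runge–Kutta, fits every trace with the unifying **Φ-order model**

    C_j(t) = C_inf,j + Σ_i ω_ij · Log10(1 + cc · e^(−k_ij t))

(one shared coupling factor `cc` per mechanism, shared rate constants
across species), and inverts fitted traces for all intrinsic parameters:
the absorption coefficients by a linear Beer–Lambert system at
well-conditioned timepoints, the per-step quantum yields by a linear system
of rate-law equations. Initial rates — invariant across the fit's many
equally good minima — serve as the photokinetic metric throughout, and
inverting the reactant's initial-rate law turns any standardized
photoreaction into an actinometer ("kinactinometry").

## Worked example: a photoreversible drug

The reference system is a photoreversible couple `X ⇌ Y1` with
`εX = 12004`, `εY1 = 23123` M⁻¹cm⁻¹, quantum yields 0.062 (forward) and
0.034 (reverse), `CX0 = 1.58e-5` M, `P0 = 1.25e-5` einstein s⁻¹ dm⁻³ and a
1.65 cm path:

```r
library(phikinet)
ex <- photoreversible_example()
tr <- simulate_mechanism(ex$mechanism, ex$setup, t_end = 120, dt = 0.1)
i30 <- which(tr$times == 30)
c(CX_30s = tr$conc[i30, "X"], Atot_30s = tr$atot[i30])
#>     CX_30s.X     Atot_30s
#> 9.912741e-06 4.209540e-01
```

At 30 s the reactant is down to 9.913e-6 M and the medium's absorbance has
risen to 0.421 (the photoproduct absorbs more strongly than the reactant).
Now pretend the `ε` and `Φ` values are unknown and recover them from the
traces alone:

```r
topo <- ex$mechanism
topo$species$epsilon <- NA_real_   # unknowns
topo$steps$phi <- NA_real_
rep <- solve_intrinsics(tr, topo, ex$setup, seed = 1,
                        timepoints = c(30, 60))
rep
#> <solve_report>
#>  epsilons (M^-1 cm^-1):
#>     X    Y1
#> 12004 23123
#>  quantum yields:
#> X->Y1 Y1->X
#> 0.062 0.034
#>  timepoints: 30, 60 s; cond(eps)=12.1 cond(phi)=2.87
```

All four intrinsic parameters come back to within a few hundredths of a
percent of the values that generated the trace. The same machinery solves
branched, cyclic and consecutive mechanisms carved from the built-in
eight-species template (`scheme1_template()`), and
`kinactinometry(r0x, phi_sum, ax0)` recovers the photon flux from the
fitted initial rate once the quantum yields are standardized.

A command-line wrapper lives in `inst/cli/phikinet.R`
(`simulate | fit | solve | actinometry | sweep | fixtures`); mechanism
configs are YAML (see `?parse_mechanism`), traces are plain CSV.

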