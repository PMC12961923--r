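Package: hydropattern
Title: Molecular-Scale Hydrophobicity of Patterned Monolayer Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies molecular-scale hydrophobicity of self-assembled
    monolayers patterned with charged or polar head groups. Builds idealized
    alkanethiol monolayer slabs, generates synthetic biased ensembles
    (harmonically and linearly biased Boltzmann samples, rigid three-site
    water boxes, interfacial density grids), computes coarse-grained water
    numbers over union-of-spheres probe volumes with analytic biasing forces,
    estimates dewetting free energies by sparse sampling of the linear-bias
    response, reconstructs potentials of mean force from umbrella windows by
    the weighted histogram analysis method with bootstrap errors, evaluates
    binding free energies from Boltzmann-weighted bound/unbound integrals,
    and provides interfacial water structure analytics: geometric hydrogen
    bond detection, radial distribution functions, water orientation
    distributions, local hydrogen-bond densities, two-dimensional interfacial
    density maps and dewetted areas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    bio3d,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
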