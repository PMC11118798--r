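# Descending pain regulation network: brainstem, diencephalon and cervical
# spinal cord. 10 regions, 32 inter-region connections, 3 latent inputs
# (35 connections total). provenance "text" = edge named in the source
# text/connectivity tables; "fixture" = plausible descending-pain-modulation
# pathway added to complete the declared 32-edge set.
regions:
- {name: right dorsal horn of the sixth cervical spinal cord segment, abbrev: C6RD, n_subregions: 5}
- {name: dorsal reticular nucleus of the medulla, abbrev: DRt, n_subregions: 5}
- {name: hypothalamus, abbrev: Hypothalamus, n_subregions: 5}
- {name: locus coeruleus, abbrev: LC, n_subregions: 5}
- {name: nucleus gigantocellularis, abbrev: NGc, n_subregions: 5}
- {name: nucleus raphe magnus, abbrev: NRM, n_subregions: 5}
- {name: nucleus tractus solitarius, abbrev: NTS, n_subregions: 5}
- {name: periaqueductal gray, abbrev: PAG, n_subregions: 5}
- {name: parabrachial nuclei, abbrev: PBN, n_subregions: 5}
- {name: medial thalamus, abbrev: Thalamus, n_subregions: 5}
connections:
- {source: PBN, target: Thalamus, provenance: text}
- {source: LC, target: Hypothalamus, provenance: text}
- {source: PBN, target: Hypothalamus, provenance: text}
- {source: Hypothalamus, target: LC, provenance: text}
- {source: LC, target: Thalamus, provenance: text}
- {source: LC, target: DRt, provenance: text}
- {source: LC, target: PBN, provenance: text}
- {source: C6RD, target: Thalamus, provenance: text}
- {source: PAG, target: NTS, provenance: text}
- {source: PAG, target: LC, provenance: text}
- {source: PBN, target: LC, provenance: text}
- {source: C6RD, target: NTS, provenance: fixture}
- {source: C6RD, target: PBN, provenance: fixture}
- {source: C6RD, target: NGc, provenance: fixture}
- {source: C6RD, target: DRt, provenance: fixture}
- {source: DRt, target: C6RD, provenance: fixture}
- {source: NRM, target: C6RD, provenance: fixture}
- {source: NGc, target: C6RD, provenance: fixture}
- {source: LC, target: C6RD, provenance: fixture}
- {source: PAG, target: NRM, provenance: fixture}
- {source: PAG, target: NGc, provenance: fixture}
- {source: PAG, target: Thalamus, provenance: fixture}
- {source: Hypothalamus, target: PAG, provenance: fixture}
- {source: Hypothalamus, target: Thalamus, provenance: fixture}
- {source: NTS, target: PBN, provenance: fixture}
- {source: NTS, target: PAG, provenance: fixture}
- {source: NTS, target: LC, provenance: fixture}
- {source: PBN, target: PAG, provenance: fixture}
- {source: NRM, target: NGc, provenance: fixture}
- {source: NGc, target: NRM, provenance: fixture}
- {source: Thalamus, target: Hypothalamus, provenance: fixture}
- {source: NTS, target: Hypothalamus, provenance: fixture}
latents:
- {name: int1, targets: [C6RD]}
- {name: int2, targets: [LC]}
- {name: int3, targets: [Thalamus]}
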