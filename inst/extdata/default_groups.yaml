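# Bundled default grouping configuration.
#
# semantic_groups maps UMLS semantic-type codes (and, for convenience, the
# corresponding full type names as used in narrative examples) to the McCray
# semantic groups that aggregate the 134 UMLS semantic types into 15 groups.
# Only the types routinely emitted by SemRep predication arguments are listed;
# users may extend or replace this table.
semantic_groups:
  # Anatomy
  anst: Anatomy
  blor: Anatomy
  bpoc: Anatomy
  bsoj: Anatomy
  bdsu: Anatomy
  celc: Anatomy
  cell: Anatomy
  emst: Anatomy
  ffas: Anatomy
  tisu: Anatomy
  "Body Part, Organ, or Organ Component": Anatomy
  "Body Location or Region": Anatomy
  "Tissue": Anatomy
  "Cell": Anatomy
  # Chemicals & Drugs
  aapp: Chemicals & Drugs
  antb: Chemicals & Drugs
  bacs: Chemicals & Drugs
  bodm: Chemicals & Drugs
  chem: Chemicals & Drugs
  chvf: Chemicals & Drugs
  chvs: Chemicals & Drugs
  clnd: Chemicals & Drugs
  elii: Chemicals & Drugs
  enzy: Chemicals & Drugs
  hops: Chemicals & Drugs
  horm: Chemicals & Drugs
  imft: Chemicals & Drugs
  inch: Chemicals & Drugs
  nnon: Chemicals & Drugs
  orch: Chemicals & Drugs
  phsu: Chemicals & Drugs
  rcpt: Chemicals & Drugs
  vita: Chemicals & Drugs
  "Pharmacologic Substance": Chemicals & Drugs
  "Organic Chemical": Chemicals & Drugs
  "Amino Acid, Peptide, or Protein": Chemicals & Drugs
  "Hormone": Chemicals & Drugs
  # Disorders
  acab: Disorders
  anab: Disorders
  cgab: Disorders
  dsyn: Disorders
  emod: Disorders
  fndg: Disorders
  inpo: Disorders
  mobd: Disorders
  neop: Disorders
  patf: Disorders
  sosy: Disorders
  "Disease or Syndrome": Disorders
  "Neoplastic Process": Disorders
  "Mental or Behavioral Dysfunction": Disorders
  "Sign or Symptom": Disorders
  "Pathologic Function": Disorders
  # Genes & Molecular Sequences
  amas: Genes & Molecular Sequences
  crbs: Genes & Molecular Sequences
  gngm: Genes & Molecular Sequences
  mosq: Genes & Molecular Sequences
  nusq: Genes & Molecular Sequences
  "Gene or Genome": Genes & Molecular Sequences
  # Physiology
  biof: Physiology
  celf: Physiology
  clna: Physiology
  genf: Physiology
  menp: Physiology
  moft: Physiology
  orgf: Physiology
  ortf: Physiology
  phsf: Physiology
  "Physiologic Function": Physiology
  "Organism Function": Physiology
  # Procedures
  diap: Procedures
  edac: Procedures
  hlca: Procedures
  lbpr: Procedures
  mbrt: Procedures
  topp: Procedures
  "Therapeutic or Preventive Procedure": Procedures
  "Diagnostic Procedure": Procedures
  "Laboratory Procedure": Procedures
  # Living Beings (arguments of e.g. PROCESS_OF; no metapredication uses them)
  aggp: Living Beings
  humn: Living Beings
  grup: Living Beings
  podg: Living Beings
  popg: Living Beings
  "Patient or Disabled Group": Living Beings
  "Population Group": Living Beings

# The seven predicate groups. Keys are uppercase SemRep predicates.
predicate_groups:
  PART_OF: Physical
  LOCATION_OF: Physical
  INHIBITS: Interaction
  STIMULATES: Interaction
  INTERACTS_WITH: Interaction
  TREATS: Therapy
  PREVENTS: Therapy
  COMPARED_WITH: Therapy
  USES: Therapy
  ASSOCIATED_WITH: Causation
  CAUSES: Causation
  PREDISPOSES: Causation
  DIAGNOSES: Diagnosis
  MEASURES: Diagnosis
  AFFECTS: Affects
  AUGMENTS: Affects
  DISRUPTS: Affects
  COEXISTS_WITH: Comorbidity

# The eight metapredication families. Each family has a display name and one
# or more <semantic group, predicate group, semantic group> realizations; the
# family as a whole labels a cluster theme.
metapredications:
  - name: Body location
    triples:
      - [Anatomy, Physical, Anatomy]
      - [Anatomy, Physical, Chemicals & Drugs]
      - [Anatomy, Physical, Disorders]
  - name: Substance interaction
    triples:
      - [Chemicals & Drugs, Interaction, Chemicals & Drugs]
      - [Chemicals & Drugs, Interaction, Genes & Molecular Sequences]
  - name: Drug treatment
    triples:
      - [Chemicals & Drugs, Therapy, Disorders]
      - [Chemicals & Drugs, Therapy, Chemicals & Drugs]
  - name: Procedure treatment
    triples:
      - [Procedures, Therapy, Disorders]
      - [Procedures, Therapy, Chemicals & Drugs]
  - name: Etiology
    triples:
      - [Genes & Molecular Sequences, Causation, Disorders]
      - [Chemicals & Drugs, Causation, Disorders]
      - [Disorders, Causation, Disorders]
  - name: Diagnosis
    triples:
      - [Procedures, Diagnosis, Disorders]
      - [Procedures, Diagnosis, Chemicals & Drugs]
  - name: Affect
    triples:
      - [Disorders, Affects, Disorders]
      - [Chemicals & Drugs, Affects, Disorders]
      - [Chemicals & Drugs, Affects, Physiology]
  - name: Disease comorbidities
    triples:
      - [Disorders, Comorbidity, Disorders]

# Concept identifiers regarded as generic (too high in the concept hierarchy
# to be informative). Corpus-specific; empty by default. A concept hierarchy
# (child/parent pairs) plus generic_depth may be supplied instead.
generic_concepts: []
hierarchy: []
generic_depth: ~
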