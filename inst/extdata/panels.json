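{
  "everolimus": {
    "drug": "everolimus",
    "genes": ["PIK3CA", "PIK3CB", "AKT1", "MTOR", "FKBP1A", "RPS6KB1",
              "EIF4EBP1", "HIF1A", "TSC1", "TSC2", "AKT2", "RPTOR", "PTEN",
              "RHEB", "MLST8", "RICTOR", "VEGFA"],
    "aliases": {"FKB-12": "FKBP1A", "S6K1": "RPS6KB1", "4EBP1": "EIF4EBP1",
                "HIF1": "HIF1A"},
    "source": "17 literature-curated key genes of the mTOR pathway (upstream regulators, MTORC1/MTORC2 components, downstream effectors)"
  },
  "axitinib": {
    "drug": "axitinib",
    "genes": ["VEGFA", "VEGFB", "VEGFC", "PDGFA", "PDGFB", "FLT1", "KDR",
              "FLT4", "PDGFRA", "PDGFRB", "KIT", "KITLG", "FIGF"],
    "aliases": {"VEGFR1": "FLT1", "VEGFR2": "KDR", "VEGFR3": "FLT4",
                "FIGF": "VEGFD"},
    "source": "13 literature-curated key genes controlling angiogenesis: VEGF receptors 1-3 and their ligands, PDGF receptors/ligands, KIT/KITLG"
  },
  "trametinib": {
    "drug": "trametinib",
    "genes": ["MAP2K1", "MAP2K2", "ARAF", "BRAF", "RAF1", "MAPK3", "MAPK1",
              "MAPK10", "KRAS", "HRAS", "NRAS", "KSR1", "RAP1A"],
    "aliases": {"MEK1": "MAP2K1", "MEK2": "MAP2K2", "ERK1": "MAPK3",
                "ERK2": "MAPK1", "CRAF": "RAF1"},
    "source": "13 literature-curated key genes of the RAS/RAF/MEK/ERK cascade"
  },
  "afatinib": {
    "drug": "afatinib",
    "genes": ["EGFR", "ERBB2", "ERBB3", "ERBB4", "EGF", "TGFA", "AREG",
              "EREG", "HBEGF", "BTC", "NRG1", "NRG2", "NRG4"],
    "aliases": {},
    "source": "13 literature-curated key genes: the four HER-family receptors and their ligands"
  },
  "fgfr": {
    "drug": "fgfr",
    "genes": ["FGFR1", "FGFR2", "FGFR3", "FGFR4", "FGF1", "FGF2", "FGF3",
              "FGF4", "FGF5", "FGF6", "FGF7", "FGF8", "FGF9", "FGF10",
              "FGF13", "FGF16", "FGF17", "FGF18", "FGF19"],
    "aliases": {},
    "source": "19 key genes: FGFR1-4 plus 15 FGF ligands. The literature list truncates the ligand enumeration ('FGF ligands 1, 2, 3, 4, 5, etc.'); the 15 packaged here are FGF1-FGF10, FGF13, FGF16, FGF17, FGF18 and FGF19, chosen to include the five ligands of the published 5-gene predictor (FGF10, FGF16, FGF5, FGF2, FGF13)."
  },
  "anti-PD-1": {
    "drug": "anti-PD-1",
    "genes": ["PDL-1", "PDL-2", "PD-1", "CTLA-4", "CD28", "CD80", "CD86",
              "LAG-3", "TLR-4", "CD8A", "CD16", "FOXP3"],
    "aliases": {"PDL-1": "CD274", "PDL-2": "PDCD1LG2", "PD-1": "PDCD1",
                "CTLA-4": "CTLA4", "LAG-3": "LAG3", "TLR-4": "TLR4",
                "CD16": "FCGR3A"},
    "source": "12 immuno-oncology key genes: checkpoint axis (PD-1/PD-L1/PD-L2, CTLA-4, CD28, CD80, CD86, LAG-3, TLR-4) plus effector-infiltrate markers CD8A (cytotoxic T), CD16 (NK) and FOXP3 (T-reg)"
  }
}
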