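{
  "prevalence_overall": {
    "value": 0.0015,
    "source": "cross-sectional MS prevalence, northern populations (~100-200 per 100,000; Kaiser N. California 150/100,000)"
  },
  "prevalence_45_54": {
    "value": 0.00304,
    "source": "age-restricted prevalence 45-54y, Sundstrom et al., Sweden (304 per 100,000)"
  },
  "death_certificate_rate": {
    "value": 0.0028,
    "source": "multiple-cause-of-death study, British Columbia (MS on 0.28% of death certificates)"
  },
  "ageband_weights": {
    "value": [0.20, 0.41, 0.39],
    "source": "2010 US census resident population: <15y, 15-45y, >45y"
  },
  "mz_recurrence": {
    "value": 0.25,
    "source": "Willer et al., CCPGSMS Canadian twin study: MZ proband-wise concordance (totals row)"
  },
  "dz_recurrence": {
    "value": 0.054,
    "source": "Willer et al., CCPGSMS: DZ-twin recurrence risk"
  },
  "sib_recurrence": {
    "value": 0.029,
    "source": "Willer et al., CCPGSMS: non-twin sibling recurrence risk"
  },
  "mz_recurrence_by_sex": {
    "value": {"F": 0.34, "M": 0.067},
    "source": "Willer et al., CCPGSMS: MZ proband-wise concordance by sex"
  },
  "p_ms": {
    "value": 0.003,
    "source": "consensus lifetime MS probability from three prevalence-based estimates"
  },
  "p_f_ms_t1": {
    "value": 0.6875,
    "source": "Orton et al., Canada: F:M sex ratio 2.2 in the 1941-1945 birth epoch"
  },
  "p_f_ms_t2": {
    "value": 0.66,
    "source": "CCPGSMS case series: proportion of MS cases who are women"
  },
  "p_f_ms_t2_variants": {
    "value": {"case_series": 0.66, "orton_recent_epoch": 0.76, "from_sex_ratio_3_2": 0.76190476},
    "source": "alternative recent-epoch values: case series 0.66; Orton et al. most recent epoch 0.76; 3.2/(1+3.2)"
  },
  "sex_ratio_t1": {
    "value": 2.2,
    "source": "Orton et al., Canada: F:M ratio among MS cases, 1941-1945"
  },
  "sex_ratio_t2": {
    "value": 3.2,
    "source": "Orton et al., Canada: F:M ratio among MS cases, 1976-1980"
  },
  "p_hplus": {
    "value": 0.23,
    "source": "WTCCC controls: carriers of HLA-DRB1*15:01~DQB1*06:02~a1"
  },
  "p_hplus_ms": {
    "value": 0.50,
    "source": "WTCCC MS cases: carriers of HLA-DRB1*15:01~DQB1*06:02~a1"
  },
  "p_f": {
    "value": 0.5,
    "source": "2010 Canadian census: proportion of women in the general population"
  },
  "penetrance_range_f": {
    "value": [0.093, 0.187],
    "source": "adjusted female penetrance limits for the sex partition (shared-environment-corrected MZ concordance in women)"
  },
  "penetrance_range_m": {
    "value": [0.017, 0.034],
    "source": "adjusted male penetrance limits for the sex partition (shared-environment-corrected MZ concordance in men)"
  }
}
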