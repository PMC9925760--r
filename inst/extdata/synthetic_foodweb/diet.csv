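predator,prey,fraction
zooplankton,phytoplankton,0.6127270210068673
benthic_inverts,phytoplankton,0.33597589403927197
forage_fish,phytoplankton,0.238208828819988
shrimp,phytoplankton,0.0877915276902896
small_demersals,phytoplankton,0.06232392305474608
grouper,phytoplankton,0.045169728665308294
benthic_inverts,zooplankton,0.2727341228530195
forage_fish,zooplankton,0.47107490250059414
shrimp,zooplankton,0.35007985067691216
small_demersals,zooplankton,0.09189377202220933
grouper,zooplankton,0.10336037673984287
forage_fish,benthic_inverts,0.29071626867941786
shrimp,benthic_inverts,0.22240673974676362
small_demersals,benthic_inverts,0.17419497481990293
grouper,benthic_inverts,0.1427222867360979
shrimp,forage_fish,0.33972188188603464
small_demersals,forage_fish,0.3926925836490963
grouper,forage_fish,0.30228000509703745
small_demersals,shrimp,0.27889474645404533
grouper,shrimp,0.24096691977367507
grouper,small_demersals,0.1655006829880384
zooplankton,detritus,0.38727297899313273
benthic_inverts,detritus,0.39128998310770846
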