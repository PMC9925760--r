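group,type,tl,biomass,pb,qb,ee,catch,ba,trait,taxon,harvested,juvenile,dispersal,m0base,focal
phytoplankton,producer,1,68.53617505080847,145.94388389132712,0,0.16714735599734423,0,0,producer,phytoplankton,FALSE,FALSE,3,121.54974957490839,FALSE
zooplankton,consumer,2,10.371429043434796,37.20193659976118,253.0818594443583,0.16361121817102584,0,0,demersal,fishes,FALSE,FALSE,30,31.115282434352984,FALSE
benthic_inverts,consumer,2.5,3.843396952474678,10.054004759566219,42.268904236039695,0.49565881652527305,7.2973261350618905,0,benthic invertebrate,benthic invertebrates,TRUE,FALSE,3,5.070648659100164,FALSE
forage_fish,consumer,3,1.2574379276158174,5.570127602144665,27.916069977923677,0.47375779159021203,0.5783532853338381,0,lower TL pelagic,fishes,TRUE,FALSE,300,2.931236250476925,FALSE
shrimp,consumer,3.5,0.38340871497233664,2.6702556335949614,15.768353838533526,0.6712995417887982,0.19447591438229733,0,upper TL pelagic,fishes,TRUE,FALSE,300,0.8777142503037066,FALSE
small_demersals,consumer,4,0.1990152433208259,1.4056517926932517,7.957256481173235,0.42960266523540763,0.08505707677688372,0,upper TL pelagic,fishes,TRUE,FALSE,300,0.801780036159302,FALSE
grouper,consumer,4.5,0.046141113906148536,0.5743058070507764,4.5993757261415285,0.14287388600641865,0.0037860307728476337,0,upper TL pelagic,fishes,TRUE,FALSE,300,0.4922525046413795,TRUE
detritus,detritus,1,29.626065405149784,0,0,0.116854840160313,0,0,detritus,detritus,FALSE,FALSE,3,0,FALSE
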