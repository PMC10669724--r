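"child_id","gender","age","parental_education","parental_occupation","monthly_income","hs1","hs2","hs3","hs4","hs5","reading","rs3743205","rs11629841","rs8040756","home_supervision"
"C0001",1,9.80153424369435,5,3,5,5,5,5,5,5,0.66296925389617,"TT","TT","GG",25
"C0002",1,9.63749413075037,3,10,2,4,3,3,4,2,-0.262622510988829,"TT","TT","GG",16
"C0003",1,10.5417482421627,3,1,2,5,5,3,4,3,-1.15717443629881,"TT","GT","AG",20
"C0004",1,10.44097763295,4,6,4,4,3,4,4,4,-0.531665798805698,"TT","TT","GG",19
"C0005",1,10.2308959670684,5,8,3,4,3,4,4,4,-0.0816208612590901,"TT","TT","GG",19
"C0006",1,9.54175094110668,2,3,4,5,5,5,4,4,0.0290515225021722,"TT","TT","GG",23
"C0007",2,10.2776233307159,3,5,3,5,5,4,4,4,0.234468258784918,"TT","GT","AG",22
"C0008",2,10.1546950513532,4,1,1,1,1,2,4,3,-1.21415224027628,"TT","GT","GG",11
"C0009",2,8.51643155504703,5,6,4,3,4,3,4,5,0.435240851076746,"TT","GT","GG",19
"C0010",2,9.04217204015293,1,7,2,3,4,5,5,5,-0.00367747937192009,"TT","TT","AG",22
"C0011",2,9.97079646707866,3,8,4,5,4,4,3,3,0.354072045714437,"TT","GT","AG",19
"C0012",2,9.32595219694677,5,1,4,3,4,2,4,4,0.247935657819246,"TT","GT","AG",17
"C0013",1,8.89740630802279,3,5,5,4,3,4,3,5,-0.0560031328491243,"TT","TT","GG",19
"C0014",1,9.56287792536525,3,10,2,5,4,4,3,4,-1.18848781775525,"TT","TT","GG",20
"C0015",2,10.5187838931381,1,8,5,5,3,5,5,4,-1.31971233987723,"TT","TT","AA",22
"C0016",2,9.22949287266902,4,1,5,2,1,2,2,2,-0.243056857172094,"TT","TT","AG",9
"C0017",2,11.340538872911,5,5,2,4,4,4,4,3,-0.469465645004114,"TT","GT","GG",19
"C0018",1,9.70159249832869,2,6,5,3,4,3,4,4,-1.30048765579857,"TT","TT","GG",18
"C0019",2,10.4023878569327,2,1,5,3,5,4,4,4,-1.13345137328772,"TT","TT","GG",20
"C0020",2,10.3140939098688,3,2,4,5,4,2,5,5,0.501970930458427,"TT","GT","AG",21
"C0021",1,9.45388866987399,4,5,3,2,2,2,3,4,-0.731296609621883,"TT","GT","GG",13
"C0022",2,10.2098025887738,3,6,2,5,4,3,3,4,-0.0637370138682583,"TT","TT","GG",19
"C0023",2,10.6040407359391,3,2,4,3,4,4,5,4,-1.37599088535824,"TT","TT","GG",20
"C0024",2,9.37591193120291,5,7,1,5,5,5,5,5,-0.2713205852362,"TT","GT","GG",25
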