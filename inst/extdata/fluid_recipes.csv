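food_class,fluid,component,amount,unit,activity,activity_unit
rice_starch,SSF,electrolyte_stock,31.5,ml,,
rice_starch,SSF,salivary alpha-amylase,0.675,ml,75,U/ml
rice_starch,SSF,CaCl2 0.3 M,0.225,ml,,
rice_starch,SSF,HCl 1 M,0.2,ml,,
rice_starch,SGF,electrolyte_stock,60,ml,,
rice_starch,SGF,CaCl2 0.3 M,0.04,ml,,
rice_starch,SGF,HCl 1 M,0.22,ml,,
rice_starch,SIF,electrolyte_stock,44,ml,,
rice_starch,SIF,pancreatic alpha-amylase,2.73,ml,170.5,U/ml
rice_starch,SIF,glucoamylase,2.308,g,,
rice_starch,SIF,CaCl2 0.3 M,0.16,ml,,
rice_cream_basic,SSF,electrolyte_stock,31.5,ml,,
rice_cream_basic,SSF,salivary alpha-amylase,0.675,ml,75,U/ml
rice_cream_basic,SSF,CaCl2 0.3 M,0.225,ml,,
rice_cream_basic,SSF,HCl 1 M,0.04,ml,,
rice_cream_basic,SGF,electrolyte_stock,60,ml,,
rice_cream_basic,SGF,pepsin,47.33,mg,1000,U/ml
rice_cream_basic,SGF,CaCl2 0.3 M,0.04,ml,,
rice_cream_basic,SGF,HCl 1 M,1.945,ml,,
rice_cream_basic,SIF,electrolyte_stock,44,ml,,
rice_cream_basic,SIF,pancrelipase,115.425,mg,,
rice_cream_basic,SIF,glucoamylase,0.52,g,,
rice_cream_basic,SIF,CaCl2 0.3 M,0.16,ml,,
rice_cream_basic,SIF,NaHCO3 1 M,0.18,ml,,
rice_cream_premium,SSF,electrolyte_stock,31.5,ml,,
rice_cream_premium,SSF,salivary alpha-amylase,0.675,ml,75,U/ml
rice_cream_premium,SSF,CaCl2 0.3 M,0.225,ml,,
rice_cream_premium,SSF,HCl 1 M,0.02,ml,,
rice_cream_premium,SGF,electrolyte_stock,60,ml,,
rice_cream_premium,SGF,pepsin,47.33,mg,1000,U/ml
rice_cream_premium,SGF,CaCl2 0.3 M,0.04,ml,,
rice_cream_premium,SGF,HCl 1 M,1.33,ml,,
rice_cream_premium,SIF,electrolyte_stock,44,ml,,
rice_cream_premium,SIF,pancrelipase,115.425,mg,,
rice_cream_premium,SIF,glucoamylase,0.52,g,,
rice_cream_premium,SIF,CaCl2 0.3 M,0.16,ml,,
rice_cream_premium,SIF,HCl 1 M,0.02,ml,,
rice_cream_premium,SIF,NaHCO3 1 M,0.02,ml,,
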