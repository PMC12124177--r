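model,term,estimate,lcl90,ucl90,test,evidence,p
landscape_age,sex_male,0.410,0.188,0.633,greater_than_female,1249,0.999
landscape_age,season_hunting,1.12,0.734,1.59,greater_than_autumn,Inf,1.00
landscape_age,season_winter,0.647,0.243,1.11,greater_than_autumn,399,0.997
landscape_age,phi_grf,0.00423,0.00149,0.00925,,,
landscape_age,tau2,0.378,0.143,0.759,,,
home_range_age,sex_male,0.400,0.158,0.659,greater_than_female,269,0.996
home_range_age,season_hunting,1.10,0.710,1.56,greater_than_autumn,Inf,1.00
home_range_age,season_winter,0.553,0.141,1.01,greater_than_autumn,80.9,0.987
home_range_age,pc1,-0.118,-0.224,-0.0185,less_than_intercept,49.7,0.980
home_range_age,phi_grf,0.00323,0.000508,0.00788,,,
home_range_age,tau2,0.607,0.222,1.50,,,
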