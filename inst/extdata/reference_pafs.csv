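age_group,disease,icd10,male_2004,male_2015,male_delta,female_2004,female_2015,female_delta
<15,Colorectal cancer,C20,36.7,32.1,-4.6,35.6,30.6,-5.0
<15,Esophagus cancer,C15,52.9,48.3,-4.6,51.7,46.7,-5.0
<15,Stomach cancer,C16,19.1,16.5,-2.6,18.5,15.7,-2.8
<15,Hepatocellular cancer,C22,44.3,39.8,-4.4,43.1,38.3,-4.8
<15,Larynx cancer,C32,59.3,55.0,-4.3,58.1,53.4,-4.7
<15,Oral cancer,C00-C14,59.3,55.0,-4.3,58.1,53.4,-4.7
<15,Pancreas cancer,C25,23.9,20.7,-3.2,23.1,19.6,-3.5
<15,Prostate cancer,C61,10.9,9.2,-1.7,NA,NA,NA
<15,Lung cancer,C34,25.4,21.8,-3.6,24.5,20.7,-3.8
<15,Type 2 diabetes,E10-E14,20.5,17.6,-2.9,19.8,16.7,-3.2
<15,Ischemic stroke,I63,33.5,29.2,-4.3,32.4,27.8,-4.6
<15,Heart failure,I50,33.5,29.2,-4.3,32.4,27.8,-4.6
<15,Ischemic heart disease,I20-I25,33.5,29.2,-4.3,32.4,27.8,-4.6
15-34,Colorectal cancer,C20,46.8,43.3,-3.5,40.1,36.6,-3.5
15-34,Esophagus cancer,C15,61.8,58.9,-2.9,56.0,52.7,-3.3
15-34,Stomach cancer,C16,25.1,23.0,-2.2,21.1,19.0,-2.1
15-34,Hepatocellular cancer,C22,53.2,50.2,-3.0,47.3,44.0,-3.3
15-34,Larynx cancer,C32,67.4,64.8,-2.6,62.1,59.1,-3.0
15-34,Oral cancer,C00-C14,67.4,64.8,-2.6,62.1,59.1,-3.0
15-34,Pancreas cancer,C25,31.4,28.7,-2.7,26.3,23.7,-2.6
15-34,Prostate cancer,C61,15.3,13.7,-1.6,NA,NA,NA
15-34,Lung cancer,C34,33.7,30.7,-3.0,28.1,25.1,-3.0
15-34,Type 2 diabetes,E10-E14,27.7,25.1,-2.6,22.8,20.3,-2.5
15-34,Ischemic stroke,I63,43.2,39.8,-3.4,36.7,33.2,-3.5
15-34,Heart failure,I50,43.2,39.8,-3.4,36.7,33.2,-3.5
15-34,Ischemic heart disease,I20-I25,43.2,39.8,-3.4,36.7,33.2,-3.5
35-54,Colorectal cancer,C20,43.2,39.7,-3.5,34.2,31.9,-2.3
35-54,Esophagus cancer,C15,58.7,55.7,-3.0,50.3,48.3,-2.0
35-54,Stomach cancer,C16,23.0,20.8,-2.2,17.7,16.4,-1.3
35-54,Hepatocellular cancer,C22,50.1,47.0,-3.1,41.8,39.7,-2.1
35-54,Larynx cancer,C32,64.6,61.8,-2.7,56.8,55.0,-1.8
35-54,Oral cancer,C00-C14,64.6,61.8,-2.7,56.8,55.0,-1.8
35-54,Pancreas cancer,C25,28.7,26.0,-2.7,22.1,20.5,-1.6
35-54,Prostate cancer,C61,13.7,12.1,-1.6,NA,NA,NA
35-54,Lung cancer,C34,30.7,27.7,-3.0,23.4,21.6,-1.8
35-54,Type 2 diabetes,E10-E14,25.1,22.5,-2.6,18.9,17.4,-1.5
35-54,Ischemic stroke,I63,39.7,36.3,-3.4,31.1,28.9,-2.2
35-54,Heart failure,I50,39.7,36.3,-3.4,31.1,28.9,-2.0
35-54,Ischemic heart disease,I20-I25,39.7,36.3,-3.4,31.1,28.9,-2.2
55-64,Colorectal cancer,C20,38.7,36.1,-2.6,30.8,31.2,0.3
55-64,Esophagus cancer,C15,54.7,52.3,-2.4,47.1,47.6,0.5
55-64,Stomach cancer,C16,20.3,18.7,-1.5,15.8,16.0,0.2
55-64,Hepatocellular cancer,C22,46.0,43.7,-2.4,38.6,39.0,0.4
55-64,Larynx cancer,C32,60.9,58.7,-2.2,53.8,54.4,0.6
55-64,Oral cancer,C00-C14,60.9,58.7,-2.2,53.8,54.4,0.6
55-64,Pancreas cancer,C25,25.3,23.4,-1.9,19.7,19.9,0.2
55-64,Prostate cancer,C61,11.7,10.7,-1.0,NA,NA,NA
55-64,Lung cancer,C34,27.0,24.8,-2.2,20.8,21.0,0.2
55-64,Type 2 diabetes,E10-E14,21.9,20.1,-1.8,16.8,16.9,0.1
55-64,Ischemic stroke,I63,35.3,32.9,-2.4,27.9,28.2,0.3
55-64,Heart failure,I50,35.3,32.9,-2.4,27.9,28.2,0.3
55-64,Ischemic heart disease,I20-I25,35.3,32.9,-2.4,27.9,28.2,0.3
65-74,Colorectal cancer,C20,35.9,37.3,1.4,31.0,29.4,-1.6
65-74,Esophagus cancer,C15,52.2,53.3,1.1,47.1,45.6,-1.5
65-74,Stomach cancer,C16,18.6,19.5,0.9,15.9,15.0,-0.9
65-74,Hepatocellular cancer,C22,43.5,44.7,1.2,38.7,37.2,-1.5
65-74,Larynx cancer,C32,58.6,59.6,1.0,53.8,52.4,-1.4
65-74,Oral cancer,C00-C14,58.6,59.6,1.0,53.8,52.4,-1.4
65-74,Pancreas cancer,C25,23.3,24.4,1.1,19.9,18.7,-1.2
65-74,Prostate cancer,C61,10.6,11.2,0.6,NA,NA,NA
65-74,Lung cancer,C34,24.7,25.9,1.2,21.0,19.7,-1.3
65-74,Type 2 diabetes,E10-E14,20.0,21.0,1.0,16.9,15.8,-1.1
65-74,Ischemic stroke,I63,32.7,34.0,1.3,28.1,26.6,-1.6
65-74,Heart failure,I50,32.7,34.0,1.3,28.1,26.6,-1.5
65-74,Ischemic heart disease,I20-I25,32.7,34.0,1.3,28.1,26.6,-1.5
75+,Colorectal cancer,C20,34.6,34.3,-0.3,28.2,30.7,2.5
75+,Esophagus cancer,C15,50.7,50.6,-0.1,43.8,46.9,3.1
75+,Stomach cancer,C16,17.9,17.7,-0.2,14.4,15.7,1.3
75+,Hepatocellular cancer,C22,42.1,41.9,-0.2,35.7,38.5,2.8
75+,Larynx cancer,C32,57.2,57.1,-0.1,50.6,53.7,3.1
75+,Oral cancer,C00-C14,57.2,57.1,-0.1,50.6,53.7,3.1
75+,Pancreas cancer,C25,22.4,22.2,-0.2,18.0,19.6,1.6
75+,Prostate cancer,C61,10.2,10.0,-0.2,NA,NA,NA
75+,Lung cancer,C34,23.8,23.5,-0.3,19.0,20.7,1.7
75+,Type 2 diabetes,E10-E14,19.2,18.9,-0.3,15.2,16.6,1.4
75+,Ischemic stroke,I63,31.5,31.2,-0.3,25.5,27.8,2.3
75+,Heart failure,I50,31.5,31.2,-0.3,25.5,27.8,2.3
75+,Ischemic heart disease,I20-I25,31.5,31.2,-0.3,25.5,27.8,2.3
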