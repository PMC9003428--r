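method,subject,lda,lr,svm
lasso_selected,1,72.6,69.1,95.7
lasso_selected,2,75.7,76.7,95.9
lasso_selected,3,74.6,83,95.2
lasso_selected,4,68,67.4,85.4
lasso_selected,5,71.9,72.4,91.3
lasso_selected,6,68,70.4,95.2
lasso_selected,7,75.9,74.6,95.4
lasso_selected,8,62.6,62.2,75.9
lasso_selected,9,69.8,69.8,91.3
features_mpv,1,65.5,63.9,75.5
features_mpv,2,66.5,65.2,72.4
features_mpv,3,63.9,62.8,70.4
features_mpv,4,66.9,68.1,68.9
features_mpv,5,66.7,66.7,71.5
features_mpv,6,61.9,65.7,71.3
features_mpv,7,63.9,64.8,71.7
features_mpv,8,66.5,66.5,71.7
features_mpv,9,68.1,67.4,81.5
features_mpvs,1,65.4,65.2,78.1
features_mpvs,2,66.5,69.4,78.5
features_mpvs,3,64.6,63,71.9
features_mpvs,4,65,65.9,73
features_mpvs,5,66.1,65.4,74.8
features_mpvs,6,61.5,65.9,73.5
features_mpvs,7,62.8,64.1,72.6
features_mpvs,8,66.3,68,85.2
features_mpvs,9,67.6,68,85.2
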