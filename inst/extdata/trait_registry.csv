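trait,group,dim,description
area,area,2,number of root pixels
n_objects,object_count,0,number of disconnected root objects (8-connected)
total_length,total_length,1,total root length: sum of skeleton step lengths (1 axial / sqrt(2) diagonal)
surface_area,surface_area,2,total root surface area from the per-step cylinder model
volume,volume,3,total root volume from the per-step cylinder model
n_branch_points,branch_and_end_points,0,skeleton pixels with >= 3 neighbors (bifurcations)
n_end_points,branch_and_end_points,0,skeleton pixels with exactly 1 neighbor (root tips)
branch_points_per_length,branch_and_end_points,-1,branch points per unit root length
end_points_per_length,branch_and_end_points,-1,end points per unit root length
x_profile_mean,x_distribution,1,mean of the per-column root-pixel-count profile
x_profile_median,x_distribution,1,median of the per-column profile
x_profile_std,x_distribution,1,standard deviation of the per-column profile
x_profile_skewness,x_distribution,0,skewness of the per-column profile
x_profile_kurtosis,x_distribution,0,excess kurtosis of the per-column profile
x_profile_min,x_distribution,1,minimum of the per-column profile
x_profile_p5,x_distribution,1,5th percentile of the per-column profile
x_profile_p25,x_distribution,1,25th percentile of the per-column profile
x_profile_p75,x_distribution,1,75th percentile of the per-column profile
x_profile_p95,x_distribution,1,95th percentile of the per-column profile
x_profile_max,x_distribution,1,maximum of the per-column profile
x_profile_boot_lo,x_distribution,1,bootstrap 95% interval of the profile mean: lower bound
x_profile_boot_hi,x_distribution,1,bootstrap 95% interval of the profile mean: upper bound
y_profile_mean,y_distribution,1,mean of the per-row root-pixel-count profile
y_profile_median,y_distribution,1,median of the per-row profile
y_profile_std,y_distribution,1,standard deviation of the per-row profile
y_profile_skewness,y_distribution,0,skewness of the per-row profile
y_profile_kurtosis,y_distribution,0,excess kurtosis of the per-row profile
y_profile_min,y_distribution,1,minimum of the per-row profile
y_profile_p5,y_distribution,1,5th percentile of the per-row profile
y_profile_p25,y_distribution,1,25th percentile of the per-row profile
y_profile_p75,y_distribution,1,75th percentile of the per-row profile
y_profile_p95,y_distribution,1,95th percentile of the per-row profile
y_profile_max,y_distribution,1,maximum of the per-row profile
y_profile_boot_lo,y_distribution,1,bootstrap 95% interval of the profile mean: lower bound
y_profile_boot_hi,y_distribution,1,bootstrap 95% interval of the profile mean: upper bound
width_mean,width,1,mean local root width over skeleton pixels
width_median,width,1,median local root width
width_std,width,1,standard deviation of local root width
width_skewness,width,0,skewness of local root width
width_kurtosis,width,0,excess kurtosis of local root width
width_min,width,1,minimum local root width
width_p5,width,1,5th percentile of local root width
width_p25,width,1,25th percentile of local root width
width_p75,width,1,75th percentile of local root width
width_p95,width,1,95th percentile of local root width
width_max,width,1,maximum local root width
width_boot_lo,width,1,bootstrap 95% interval of mean width: lower bound
width_boot_hi,width,1,bootstrap 95% interval of mean width: upper bound
orientation_deg,orientation,0,best-fit-ellipse principal axis angle from vertical (degrees)
eccentricity,orientation,0,eccentricity of the best-fit ellipse of the root pixels
step_angle_mean,orientation,0,mean skeleton step angle from vertical (degrees)
step_angle_median,orientation,0,median skeleton step angle
step_angle_std,orientation,0,standard deviation of skeleton step angles
step_angle_skewness,orientation,0,skewness of skeleton step angles
step_angle_kurtosis,orientation,0,excess kurtosis of skeleton step angles
step_angle_p25,orientation,0,25th percentile of skeleton step angles
step_angle_p75,orientation,0,75th percentile of skeleton step angles
step_angle_min,orientation,0,minimum skeleton step angle
step_angle_max,orientation,0,maximum skeleton step angle
step_angle_boot_lo,orientation,0,bootstrap 95% interval of mean step angle: lower bound
step_angle_boot_hi,orientation,0,bootstrap 95% interval of mean step angle: upper bound
hull_area,convex_hull,2,pixel area of the convex hull of the root system
hull_perimeter,convex_hull,1,perimeter of the convex hull polygon
solidity,convex_hull,0,root area divided by convex hull area
hull_eq_diameter,convex_hull,1,diameter of the circle with the hull area
hull_max_diameter,convex_hull,1,maximum distance between hull vertices (max Feret diameter)
bbox_height,extent,1,bounding-box height of the root system
bbox_width,extent,1,bounding-box width of the root system
bbox_aspect,extent,0,bounding-box height / width
bbox_fill,extent,0,root area divided by bounding-box area
centroid_row,extent,1,row (depth) coordinate of the root-pixel centroid
centroid_col,extent,1,column coordinate of the root-pixel centroid
max_rooting_depth,extent,1,deepest image row containing a root pixel
min_root_row,extent,1,shallowest image row containing a root pixel
max_radial_extent,extent,1,maximum root-pixel distance from the centroid
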